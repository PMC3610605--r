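# Independent oracles used across the suite.

# Edge-simple path enumeration by explicit segment-set recursion over an
# adjacency list; independent of enumerate_paths()'s implementation.
oracle_paths <- function(segments, from = "S", to = "T") {
  adj <- list()
  for (i in seq_len(nrow(segments))) {
    a <- segments$node_a[i]; b <- segments$node_b[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(nb = b, id = i))
    adj[[b]] <- rbind(adj[[b]], data.frame(nb = a, id = i))
  }
  out <- list()
  recurse <- function(v, used) {
    if (v == to) {
      out[[length(out) + 1L]] <<- used
      return(invisible())
    }
    av <- adj[[v]]
    if (is.null(av)) return(invisible())
    for (r in seq_len(nrow(av))) {
      if (!(av$id[r] %in% used)) recurse(av$nb[r], c(used, av$id[r]))
    }
  }
  recurse(from, integer(0))
  out
}

# wrap a bare segment table as a minimal trail_network for enumerate_paths()
toy_network <- function(segments) {
  nodes <- unique(c(segments$node_a, segments$node_b))
  net <- list(
    nodes = data.frame(id = nodes, x = 0, y = 0,
                       kind = ifelse(nodes == "S", "start_area",
                              ifelse(nodes == "T", "target_area", "bifurcation"))),
    segments = segments, polylines = list(), corridor_width = 9,
    config_label = "S", loops = 3L, area_diameter = 22.5,
    extent = c(0, 140, 0, 105))
  class(net) <- "trail_network"
  net
}

seg_table <- function(ids, a, b, len) {
  data.frame(id = ids, node_a = a, node_b = b, length_cm = len,
             stringsAsFactors = FALSE)
}
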