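# Analysis pipeline: per-segment intensity series, usage calls, collective
# path classification.

#' Per-segment intensity/usage time series
#'
#' Computes, for every 1 Hz time point, the total pheromone intensity on each
#' segment and whether the segment counts as used (total strictly above the
#' threshold). Accepts either the per-second usage matrix produced by
#' [simulate_arena()] or a list of [pheromone_field()] snapshots plus
#' [segment_masks()].
#'
#' @param x `nseg x T` matrix of per-segment totals (rownames = segment ids),
#'   or a list of `pheromone_field` snapshots.
#' @param masks result of [segment_masks()]; required when `x` is a field list.
#' @param threshold usage threshold in pixel-sum units.
#' @param times optional times (s); default `0, 1, ...`.
#' @return data.frame of class `segment_usage_series`: `t`, `segment`,
#'   `intensity`, `used`, with the threshold as an attribute.
#' @export
usage_series <- function(x, masks = NULL, threshold = 50000, times = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    if (is.null(masks)) stop("masks are required for field snapshots")
    nm <- names(masks$masks)
    m <- vapply(x, function(f) {
      stopifnot(inherits(f, "pheromone_field"))
      if (length(f$grid) != length(masks$assignment)) {
        stop("field raster and masks have different shapes")
      }
      vapply(masks$masks, function(idx) sum(f$grid[idx]), numeric(1))
    }, numeric(length(nm)))
    m <- matrix(m, nrow = length(nm), dimnames = list(nm, NULL))
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) stop("usage matrix needs segment ids as rownames")
  }
  if (is.null(times)) times <- seq_len(ncol(m)) - 1
  out <- data.frame(
    t = rep(times, each = nrow(m)),
    segment = rep(rownames(m), times = ncol(m)),
    intensity = as.vector(m),
    stringsAsFactors = FALSE)
  out$used <- out$intensity > threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("segment_usage_series", "data.frame")
  out
}

#' Classify the collectively selected path at one time point
#'
#' Greedy trace of the most-marked route: starting from the start area, repeat
#' following the outgoing segment with the highest total intensity (never
#' re-entering the segment just traversed) until reaching (a) a bifurcation
#' whose candidate segments are both at or below the threshold - category
#' `"NONE"`; (b) a previously visited bifurcation (the trace's own start
#' included) - category `"LOOP"`; or (c) the target area - a numeric category
#' equal to the number of segments traced. The first step requires the chosen
#' segment to exceed the threshold (an unmarked network yields `"NONE"`).
#' Exact intensity ties are broken toward the alphabetically lower segment id
#' (with a warning).
#'
#' @param intensities named numeric vector of per-segment totals.
#' @param network a [build_network()] object.
#' @param threshold usage threshold.
#' @return list of class `path_classification`: `category` (character, one of
#'   "4", "6", "8", "10", "LOOP", "NONE"), `segments` (traced ids).
#' @export
classify_path <- function(intensities, network, threshold = 50000) {
  stopifnot(inherits(network, "trail_network"))
  segs <- network$segments
  if (is.null(names(intensities)) || !all(segs$id %in% names(intensities))) {
    stop("intensities must be named with all segment ids")
  }
  visited <- "S"
  node <- "S"
  prev <- NA_character_
  trace <- character(0)
  repeat {
    cand <- segs$id[(segs$node_a == node | segs$node_b == node)]
    cand <- setdiff(cand, prev)
    iv <- intensities[cand]
    if (length(cand) == 0L || max(iv) <= threshold) {
      return(structure(list(category = "NONE", segments = trace),
                       class = "path_classification"))
    }
    if (sum(iv == max(iv)) > 1L) {
      warning("intensity tie at node ", node, "; choosing lower segment id")
      nxt <- sort(cand[iv == max(iv)])[1]
    } else {
      nxt <- cand[which.max(iv)]
    }
    trace <- c(trace, nxt)
    r <- segs[segs$id == nxt, ]
    node <- if (r$node_a == node) r$node_b else r$node_a
    prev <- nxt
    if (node == "T") {
      return(structure(list(category = as.character(length(trace)),
                            segments = trace),
                       class = "path_classification"))
    }
    if (node %in% visited) {
      return(structure(list(category = "LOOP", segments = trace),
                       class = "path_classification"))
    }
    visited <- c(visited, node)
  }
}

#' @export
print.path_classification <- function(x, ...) {
  cat(sprintf("<path_classification> %s (%s)\n", x$category,
              paste(x$segments, collapse = " > ")))
  invisible(x)
}

#' Per-second collective path categories for a whole run
#'
#' Applies [classify_path()] to every column of a per-segment usage matrix.
#'
#' @param usage `nseg x T` matrix (rownames = segment ids) of totals.
#' @param network a [build_network()] object.
#' @param threshold usage threshold.
#' @return character vector of categories, one per second.
#' @export
classify_series <- function(usage, network, threshold = 50000) {
  usage <- as.matrix(usage)
  vapply(seq_len(ncol(usage)), function(j) {
    suppressWarnings(
      classify_path(stats::setNames(usage[, j], rownames(usage)),
                    network, threshold)$category)
  }, character(1))
}

#' Mean number of segments in use over a time window
#'
#' @param usage `nseg x T` matrix of per-segment totals (1 Hz columns).
#' @param threshold usage threshold.
#' @param from,to window in seconds (defaults: after initial dispersion,
#'   `t > 500`, to the end).
#' @return mean count of segments whose total exceeds the threshold.
#' @export
segments_used_plateau <- function(usage, threshold = 50000, from = 500,
                                  to = Inf) {
  usage <- as.matrix(usage)
  tt <- seq_len(ncol(usage)) - 1
  keep <- tt > from & tt <= to
  if (!any(keep)) stop("empty plateau window")
  mean(colSums(usage[, keep, drop = FALSE] > threshold))
}
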