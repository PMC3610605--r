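net_S <- build_network("S")
net_A <- build_network("A")

test_that("the three-loop maze satisfies its published constraints", {
  for (net in list(net_S, net_A)) {
    p <- enumerate_paths(net)
    expect_equal(nrow(p), 7L)
    expect_setequal(unique(p$n_segments), c(4L, 6L, 8L, 10L))
    expect_equal(min(p$length_cm), 86)
    expect_equal(max(p$length_cm), 178)
    # sorted by length
    expect_true(!is.unsorted(p$length_cm))
    # no path reuses a segment; endpoints are the areas
    for (sg in p$segments) expect_equal(anyDuplicated(sg), 0L)
    expect_equal(p$length_cm,
                 vapply(p$segments, function(sg)
                   sum(net$segments$length_cm[match(sg, net$segments$id)]),
                   numeric(1)))
  }
  expect_equal(net_S$corridor_width, 9)
  expect_equal(net_S$area_diameter, 22.5)
})

test_that("S and A share topology and per-segment lengths exactly", {
  expect_equal(net_S$segments$id, net_A$segments$id)
  expect_equal(net_S$segments$length_cm, net_A$segments$length_cm)
  expect_lt(abs(sum(net_S$segments$length_cm) - sum(net_A$segments$length_cm)),
            1e-9)
})

test_that("bifurcation deviations are 60/60 in S and 30/30 or 30/120 in A", {
  expect_true(all(abs(net_S$branch_angles$deviation_deg - 60) < 1e-6))
  byA <- split(net_A$branch_angles, paste(net_A$branch_angles$node,
                                          net_A$branch_angles$incoming))
  for (side in byA) {
    devs <- sort(round(side$deviation_deg, 6))
    expect_true(identical(devs, c(30, 30)) || identical(devs, c(30, 120)))
  }
  # every bifurcation has both a symmetric side and asymmetric sides
  for (n in unique(net_A$branch_angles$node)) {
    ba <- net_A$branch_angles[net_A$branch_angles$node == n, ]
    kinds <- vapply(split(ba, ba$incoming),
                    function(s) diff(range(s$deviation_deg)) > 1, logical(1))
    expect_true(any(kinds) && any(!kinds))
  }
})

test_that("corridor centerlines match stored lengths and fit the arena", {
  for (net in list(net_S, net_A)) {
    for (i in seq_len(nrow(net$segments))) {
      p <- net$polylines[[net$segments$id[i]]]
      arc <- sum(sqrt(rowSums(diff(p)^2)))
      expect_lt(abs(arc - net$segments$length_cm[i]), 0.1)
      expect_true(all(p[, 1] >= 4.5 & p[, 1] <= 135.5))
      expect_true(all(p[, 2] >= 4.5 & p[, 2] <= 100.5))
    }
  }
})

test_that("path enumeration equals the segment-set recursion oracle", {
  for (net in list(net_S, net_A)) {
    oracle <- oracle_paths(net$segments)
    p <- enumerate_paths(net)
    expect_equal(length(oracle), nrow(p))
    canon <- function(idx) paste(sort(idx), collapse = "|")
    o_set <- sort(vapply(oracle, canon, character(1)))
    e_set <- sort(vapply(p$segments, function(sg)
      canon(match(sg, net$segments$id)), character(1)))
    expect_equal(o_set, e_set)
  }
})

test_that("enumeration agrees with the oracle on small ad-hoc graphs", {
  # single corridor
  toy1 <- toy_network(seg_table("e1", "S", "T", 10))
  p1 <- enumerate_paths(toy1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$n_segments, 1L)
  # double bridge
  toy2 <- toy_network(seg_table(c("a", "b"), c("S", "S"), c("T", "T"), c(5, 9)))
  expect_equal(nrow(enumerate_paths(toy2)), 2L)
  # theta with a chord and a revisitable crossing
  toy3 <- toy_network(seg_table(
    c("e1", "e2", "e3", "e4", "e5"),
    c("S", "X", "X", "Y", "S"),
    c("X", "Y", "Y", "T", "Y"),
    c(4, 3, 3, 4, 6)))
  expect_equal(nrow(enumerate_paths(toy3)), length(oracle_paths(toy3$segments)))
  # disconnected target
  toy4 <- toy_network(seg_table(c("e1", "e2"), c("S", "X"), c("A", "T"), c(3, 3)))
  expect_error(enumerate_paths(toy4), "no start-to-target path")
})

test_that("unsupported loop counts are rejected; 4-loop variant stays coherent", {
  expect_error(build_network("S", 5L), "unsupported")
  net4 <- build_network("A", 4L)
  p4 <- enumerate_paths(net4)
  expect_gt(nrow(p4), 7L)
  expect_equal(length(oracle_paths(net4$segments)), nrow(p4))
})

test_that("segment masks partition corridor cells and track polygon areas", {
  m <- segment_masks(net_S, c(400L, 300L))
  # pairwise disjoint and consistent with the assignment matrix
  all_cells <- unlist(m$masks)
  expect_equal(anyDuplicated(all_cells), 0L)
  expect_equal(sum(m$assignment > 0), length(all_cells))
  # union ~ corridor area outside the areas: compare against an independent
  # point-in-polygon scan on a staggered grid
  set.seed(42)
  pts <- cbind(runif(20000, 0, 140), runif(20000, 0, 105))
  sd <- trailnet:::.domain_sd(net_S, pts)
  in_hexes <- rep(FALSE, nrow(pts))
  ar <- net_S$nodes[net_S$nodes$kind != "bifurcation", ]
  for (i in seq_len(nrow(ar))) {
    in_hexes <- in_hexes | trailnet:::.in_hexagon(pts, c(ar$x[i], ar$y[i]),
                                                 net_S$area_diameter)
  }
  frac_scan <- mean(sd > 0 & !in_hexes)
  frac_mask <- length(all_cells) / length(m$assignment)
  expect_lt(abs(frac_scan - frac_mask) / frac_mask, 0.02)
  # uniform raster of ones: per-segment totals proportional to mask areas
  f <- pheromone_field(400L, 300L, net_S$extent)
  f$grid[] <- 1
  u <- usage_series(list(f), m, threshold = 0)
  expect_equal(u$intensity, lengths(m$masks)[u$segment], ignore_attr = TRUE)
  # too coarse a raster cannot separate 9 cm corridors
  expect_error(segment_masks(net_S, c(40L, 30L)), "too coarse")
})

test_that("network JSON round trip preserves the geometry", {
  tmp <- tempfile(fileext = ".json")
  write_network_json(net_A, tmp)
  back <- read_network_json(tmp)
  expect_equal(back$config_label, "A")
  expect_equal(back$segments$length_cm, net_A$segments$length_cm)
  expect_equal(back$polylines[["sSA"]], net_A$polylines[["sSA"]],
               tolerance = 1e-8, ignore_attr = TRUE)
  unlink(tmp)
})
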