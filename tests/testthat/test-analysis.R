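net <- build_network("S")
masks <- segment_masks(net, c(400L, 300L))
paths <- enumerate_paths(net)

test_that("usage flags require strictly exceeding the threshold", {
  m <- matrix(0, nrow(net$segments), 3,
              dimnames = list(net$segments$id, NULL))
  m["sSB", ] <- c(49999, 50000, 50001)
  u <- usage_series(m)
  flags <- u$used[u$segment == "sSB"]
  expect_equal(flags, c(FALSE, FALSE, TRUE))
  expect_true(all(!u$used[u$segment != "sSB"]))
  expect_equal(u$t[1:2], c(0, 0) + c(0, 0))
})

test_that("usage series from field snapshots equals brute-force cell sums", {
  lv <- setNames(c(60000, 55000), c("sSB", "sVB"))
  f <- canned_field(net, lv, masks, c(400L, 300L))
  u <- usage_series(list(f), masks)
  for (s in names(lv)) {
    expect_equal(u$intensity[u$segment == s], sum(f$grid[masks$masks[[s]]]))
    expect_lt(abs(u$intensity[u$segment == s] - lv[[s]]), 1e-6)
  }
  expect_setequal(u$segment[u$used], names(lv))
})

test_that("an empty network classifies as NONE and a marked cycle as LOOP", {
  zero <- setNames(numeric(nrow(net$segments)), net$segments$id)
  expect_equal(classify_path(zero, net)$category, "NONE")
  # a marked route that returns to a visited bifurcation:
  # S -> B -> U -> D -> V -> B closes a loop at B
  lv <- zero
  lv[c("sSB", "sUB", "sUD", "sVD", "sVB")] <- c(90, 80, 70, 65, 60) * 1000
  cl <- classify_path(lv, net)
  expect_equal(cl$category, "LOOP")
  expect_equal(cl$segments, c("sSB", "sUB", "sUD", "sVD", "sVB"))
})

test_that("each of the seven canned path fixtures classifies to its category", {
  zero <- setNames(numeric(nrow(net$segments)), net$segments$id)
  for (i in seq_len(nrow(paths))) {
    lv <- zero
    sg <- paths$segments[[i]]
    # monotone decreasing marking along the path keeps the trace on it
    lv[sg] <- seq(120000, 60000, length.out = length(sg))
    cl <- classify_path(lv, net)
    expect_equal(cl$category, as.character(paths$n_segments[i]))
    expect_equal(cl$segments, sg)
  }
})

test_that("classification ignores uniform scaling above the threshold", {
  zero <- setNames(numeric(nrow(net$segments)), net$segments$id)
  sg <- paths$segments[[4]]
  lv <- zero; lv[sg] <- seq(150000, 70000, length.out = length(sg))
  c1 <- classify_path(lv, net)
  c2 <- classify_path(lv * 3.7, net)
  expect_equal(c1$category, c2$category)
  expect_equal(c1$segments, c2$segments)
})

test_that("exact intensity ties are broken to the lower segment id with a warning", {
  zero <- setNames(numeric(nrow(net$segments)), net$segments$id)
  lv <- zero
  lv[c("sSA", "sSB")] <- 80000            # tie at the start area
  lv[c("sRAa", "sRAb", "sRE", "sTE")] <- c(70000, 60000, 65000, 60000)
  expect_warning(cl <- classify_path(lv, net), "tie")
  expect_equal(cl$segments[1], "sSA")
})

test_that("a half-marked route dead-ending in empty branches is NONE", {
  zero <- setNames(numeric(nrow(net$segments)), net$segments$id)
  lv <- zero
  lv[c("sSB", "sVB")] <- c(90000, 80000)   # stops at V: sVD/sVE unmarked
  expect_equal(classify_path(lv, net)$category, "NONE")
})

test_that("per-second classification works on simulated usage matrices", {
  sim <- simulate_arena(net, n_agents = 6, duration = 400, seed = 3,
                        record_dt = 0, raster_shape = c(400L, 300L))
  cats <- classify_series(sim$usage, net)
  expect_equal(length(cats), ncol(sim$usage))
  expect_true(all(cats %in% c("4", "6", "8", "10", "LOOP", "NONE")))
  expect_equal(cats[1], "NONE")            # nothing marked at t = 0
})

test_that("plateau summary averages the right window", {
  m <- matrix(0, 2, 1001, dimnames = list(c("a", "b"), NULL))
  m[1, ] <- 60000                         # always used
  m[2, 700:1001] <- 60000                 # used late
  expect_equal(segments_used_plateau(m, from = 500),
               mean(1 + (seq(501, 1000) >= 699)))
  expect_error(segments_used_plateau(m, from = 2000), "empty")
})
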