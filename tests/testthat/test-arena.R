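test_that("exploratory redirections follow the stated motion statistics", {
  p <- behavior_params()
  st <- list(exploratory_direction = c(1, 0), next_redirection_time = 10)
  expect_identical(exploratory_update(st, 5, p)$exploratory_direction, c(1, 0))
  # over many redirection events: bounded turns with zero mean, and
  # exponential inter-redirection intervals with mean 3 s
  set.seed(1)
  nrep <- 1e5
  turns <- numeric(nrep); gaps <- numeric(nrep)
  st <- list(exploratory_direction = c(1, 0), next_redirection_time = 0)
  ang0 <- 0
  for (i in seq_len(nrep)) {
    t <- st$next_redirection_time
    st <- exploratory_update(st, t, p)
    ang1 <- atan2(st$exploratory_direction[2], st$exploratory_direction[1])
    d <- (ang1 - ang0 + pi) %% (2 * pi) - pi
    turns[i] <- d * 180 / pi
    gaps[i] <- st$next_redirection_time - t
    ang0 <- ang1
  }
  expect_true(all(abs(turns) <= 30 + 1e-9))
  expect_lt(abs(mean(turns)), 0.2)
  expect_lt(abs(mean(gaps) - 3) / 3, 0.03)
})

test_that("avoidance and trail vectors follow the sensor geometry", {
  expect_equal(avoidance_vector(c(0, 0, 0, 0)), c(0, 0))
  # front reading 1 -> unit vector pointing backward
  expect_equal(avoidance_vector(c(0, 0, 1, 0)), c(-1, 0))
  # equal left/right readings cancel laterally (explicit vector addition)
  v <- avoidance_vector(c(0.7, 0.7, 0, 0))
  expect_equal(v[2], 0)
  expect_equal(v[1], -2 * 0.7 * cos(pi / 4))
  expect_error(avoidance_vector(c(2, 0, 0, 0)), "\\[0, 1\\]")

  expect_equal(trail_vector(0, 0), c(0, 0))
  expect_equal(trail_vector(0.4, 0.4), c(0, 0))
  expect_equal(trail_vector(0, 1), c(0, -1))   # pull to the robot's right
})

test_that("proximity readings are sigmoid in distance and vanish at range", {
  p <- behavior_params()
  expect_gt(proximity_reading(0, p), 0.99)
  expect_equal(proximity_reading(p$sigmoid_mid, p), 0.5)
  expect_equal(proximity_reading(3, p), 0)
  expect_true(all(diff(proximity_reading(seq(0, 2.9, by = 0.1), p)) < 0))
})

test_that("a free step moves exactly speed * tick and respects area markers", {
  net <- build_network("S")
  p <- behavior_params()
  # mid-corridor, no walls within sensor range, no light
  start <- net$polylines[["sSB"]][40, ]
  nxt <- net$polylines[["sSB"]][41, ]
  hd <- atan2(nxt[2] - start[2], nxt[1] - start[1])
  st <- list(position = start, heading = hd,
             exploratory_direction = c(cos(hd), sin(hd)),
             next_redirection_time = 1e9)
  out <- step_agent(st, NULL, net, p, t = 0)
  moved <- sqrt(sum((out$position - start)^2))
  expect_equal(moved, 4 * 0.05, tolerance = 1e-9)   # 2 mm per 50 ms tick
  expect_true(out$marker_on)
  # inside the start hexagon the marker is off
  sn <- net$nodes[net$nodes$id == "S", ]
  st$position <- c(sn$x, sn$y)
  out2 <- step_agent(st, NULL, net, p, t = 0)
  expect_false(out2$marker_on)
})

test_that("hard projection prevents wall crossing even without avoidance", {
  net <- build_network("S")
  p <- behavior_params(w_avoid = 0)
  pt <- net$polylines[["sSB"]][40, ]
  nxt <- net$polylines[["sSB"]][41, ]
  hd <- atan2(nxt[2] - pt[2], nxt[1] - pt[1]) + pi / 2  # straight at the wall
  st <- list(position = pt, heading = hd,
             exploratory_direction = c(cos(hd), sin(hd)),
             next_redirection_time = 1e9)
  for (i in 1:120) {
    st <- step_agent(st, NULL, net, p, t = i * 0.05)
    st$exploratory_direction <- c(cos(hd), sin(hd))  # keep pushing at the wall
    st$heading <- hd
  }
  expect_gt(trailnet:::.domain_sd(net, matrix(st$position, 1)), 0)
})

test_that("arena simulation is contained, speed-bounded and seed-deterministic", {
  net <- build_network("A")
  sim1 <- simulate_arena(net, n_agents = 4, duration = 60, seed = 9,
                         record_dt = 0.05, raster_shape = c(400L, 300L))
  sim2 <- simulate_arena(net, n_agents = 4, duration = 60, seed = 9,
                         record_dt = 0.05, raster_shape = c(400L, 300L))
  expect_identical(sim1$trajectory, sim2$trajectory)
  expect_identical(sim1$usage, sim2$usage)
  sim3 <- simulate_arena(net, n_agents = 4, duration = 60, seed = 10,
                         record_dt = 0.05, raster_shape = c(400L, 300L))
  expect_false(identical(sim1$trajectory, sim3$trajectory))
  # containment at every recorded tick
  sd <- trailnet:::.domain_sd(net, as.matrix(sim1$trajectory[, c("x", "y")]))
  expect_true(all(sd > -0.05))
  # per-tick displacement <= 2 mm (+ tiny numeric slack)
  tr <- sim1$trajectory[order(sim1$trajectory$agent, sim1$trajectory$t), ]
  d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  same <- diff(tr$agent) == 0
  expect_true(all(d[same] <= 0.2 + 1e-6))
  # markers are off exactly inside the areas
  ar <- net$nodes[net$nodes$kind != "bifurcation", ]
  inarea <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(ar))) {
    inarea <- inarea | trailnet:::.in_hexagon(as.matrix(tr[, c("x", "y")]),
                                              c(ar$x[i], ar$y[i]),
                                              net$area_diameter)
  }
  expect_equal(unname(tr$marker == 1), unname(!inarea))
})

test_that("an empty swarm produces an empty log and a zero field", {
  net <- build_network("S")
  sim <- simulate_arena(net, n_agents = 0, duration = 10, return_field = TRUE)
  expect_equal(nrow(sim$trajectory), 0L)
  expect_equal(field_total(sim$field), 0)
  expect_equal(sim$trips, 0L)
})

test_that("the symmetric Y-corridor control shows no branch preference", {
  a <- bifurcation_choice_assay(c(60, 60), n_trials = 300, seed = 21)
  expect_gt(a$n1 + a$n2, 250)
  expect_true(a$ci[1] <= 0.5 && 0.5 <= a$ci[2])
})

test_that("the 30/120 assay prefers the direct branch", {
  a <- bifurcation_choice_assay(c(30, 120), n_trials = 300, seed = 22)
  expect_lt(a$test$p.value, 0.001)       # significantly above 1/2
  expect_gt(a$proportion, 0.6)
})
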