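# Continuous-space behavioural simulator: correlated-random-walk agents with
# obstacle avoidance and trail following inside the corridor polygons, coupled
# to the pheromone raster.

#' Behavioural parameters of the arena simulator
#'
#' The agent steers by summing three weighted unit-ish vectors every 50 ms
#' tick: an exploratory heading (correlated random walk: the direction gets a
#' uniform perturbation in +/- `turn_half_deg` at exponentially distributed
#' intervals with mean `redirection_mean_s`), an avoidance vector (four
#' proximity sensors at +45/-45/0/180 degrees, readings following a sigmoid of
#' obstacle distance saturating at contact and vanishing beyond
#' `sensor_range`), and a trail-following vector (two lateral photoreceptors
#' reading the pheromone raster).
#'
#' Weights are free constants of the model: avoidance must dominate so walls
#' are never crossed, and following must dominate exploration for trails to
#' recruit. They are calibrated against the individual-choice assay.
#'
#' @param speed maximum speed, cm/s (40 mm/s).
#' @param tick control-loop period, s.
#' @param turn_half_deg half-range of the uniform redirection angle, degrees.
#' @param redirection_mean_s mean of the exponential redirection interval, s.
#' @param w_explore,w_avoid,w_follow behaviour weights (>= 0).
#' @param sensor_range proximity sensor range, cm.
#' @param sigmoid_mid,sigmoid_slope distance-to-reading sigmoid midpoint and
#'   slope, cm.
#' @param robot_radius physical agent radius, cm.
#' @param photo_offset lateral photoreceptor offset, cm.
#' @param photo_radius photoreceptor sampling radius, cm.
#' @param disc_diameter,disc_intensity,cap,tau,evap_period pheromone-field
#'   constants (see [pheromone_field()]).
#' @param deposit_period s between deposition attempts (~5 Hz tracking loop).
#' @return list of class `behavior_params`.
#' @export
behavior_params <- function(speed = 4, tick = 0.05,
                            turn_half_deg = 30, redirection_mean_s = 3,
                            w_explore = 0.5, w_avoid = 2, w_follow = 1,
                            sensor_range = 3, sigmoid_mid = 1.5,
                            sigmoid_slope = 0.3, robot_radius = 1.1,
                            photo_offset = 1.1, photo_radius = 1,
                            disc_diameter = 6, disc_intensity = 7, cap = 255,
                            tau = 1800, evap_period = 5, deposit_period = 0.2) {
  stopifnot(speed > 0, tick > 0, turn_half_deg > 0, turn_half_deg < 180,
            redirection_mean_s > 0, w_explore >= 0, w_avoid >= 0, w_follow >= 0)
  p <- as.list(environment())
  class(p) <- "behavior_params"
  p
}

#' Update the exploratory direction of a correlated random walk
#'
#' If `t` has not reached the next scheduled redirection, the direction is
#' unchanged. Otherwise a uniform angle in +/- `turn_half_deg` is added and the
#' next redirection time is drawn from an exponential distribution.
#'
#' @param state list with `exploratory_direction` (unit vector) and
#'   `next_redirection_time` (s).
#' @param t current time, s.
#' @param params a [behavior_params()].
#' @return updated state (same shape). Uses R's RNG stream.
#' @export
exploratory_update <- function(state, t, params = behavior_params()) {
  stopifnot(length(state$exploratory_direction) == 2L)
  if (t < state$next_redirection_time) return(state)
  ang <- atan2(state$exploratory_direction[2], state$exploratory_direction[1])
  ang <- ang + stats::runif(1, -params$turn_half_deg, params$turn_half_deg) * pi / 180
  state$exploratory_direction <- c(cos(ang), sin(ang))
  state$next_redirection_time <- t + stats::rexp(1, 1 / params$redirection_mean_s)
  state
}

#' Proximity reading from obstacle distance
#'
#' Sigmoid mapping: 1 at contact, ~0 at or beyond the sensor range.
#' @param d obstacle distance, cm (vectorised).
#' @param params a [behavior_params()].
#' @return readings in `[0, 1]`; exactly 0 beyond `sensor_range`.
#' @export
proximity_reading <- function(d, params = behavior_params()) {
  r <- 1 / (1 + exp((d - params$sigmoid_mid) / params$sigmoid_slope))
  r[d >= params$sensor_range] <- 0
  r
}

#' Avoidance vector from four proximity readings
#'
#' Each component points opposite its sensor's heading with magnitude equal to
#' the reading. Sensor headings (robot frame, x = forward):
#' +45, -45, 0 (front), 180 (back) degrees.
#'
#' @param readings numeric(4) in `[0, 1]`, ordered front-left, front-right,
#'   front, back.
#' @return avoidance vector `c(x, y)` in the robot frame.
#' @export
avoidance_vector <- function(readings) {
  if (length(readings) != 4L || any(readings < 0) || any(readings > 1)) {
    stop("readings must be four values in [0, 1]")
  }
  ang <- c(pi / 4, -pi / 4, 0, pi)
  c(-sum(readings * cos(ang)), -sum(readings * sin(ang)))
}

#' Trail-following vector from the two photoreceptor intensities
#'
#' @param left_light,right_light intensities in `[0, 1]`.
#' @return lateral vector `c(x, y)` in the robot frame (x = forward; left = +y).
#' @export
trail_vector <- function(left_light, right_light) {
  stopifnot(left_light >= 0, left_light <= 1, right_light >= 0, right_light <= 1)
  c(0, left_light - right_light)
}

# signed distance to the walkable domain (corridors + areas); R-side reference
.domain_sd <- function(network, pts) {
  half <- network$corridor_width / 2
  best <- rep(-Inf, nrow(pts))
  for (p in network$polylines) {
    best <- pmax(best, half - sqrt(.dist2_to_polyline(pts, p)))
  }
  ar <- network$nodes[network$nodes$kind != "bifurcation", ]
  rad <- network$area_diameter / 2
  apo <- rad * cos(pi / 6)
  for (i in seq_len(nrow(ar))) {
    x <- pts[, 1] - ar$x[i]; y <- pts[, 2] - ar$y[i]
    m <- rep(Inf, nrow(pts))
    for (k in 0:5) {
      th <- pi / 6 + k * pi / 3
      m <- pmin(m, apo - (x * cos(th) + y * sin(th)))
    }
    best <- pmax(best, m)
  }
  best
}

#' Advance one agent by one tick (reference implementation)
#'
#' Heading is set to the direction of the weighted sum of the exploratory,
#' avoidance and trail vectors (if the resultant is zero the previous heading
#' is kept); the agent advances at most `speed * tick`, with a hard
#' no-penetration rule at corridor walls; the trail marker is off inside the
#' start/target areas and on elsewhere.
#'
#' This is the single-step reference used by the tests; full simulations run
#' the same model in compiled code via [simulate_arena()].
#'
#' @param state list with `position`, `heading`, `exploratory_direction`,
#'   `next_redirection_time`.
#' @param field a [pheromone_field()] or NULL.
#' @param network a [build_network()] object.
#' @param params a [behavior_params()].
#' @param t current time, s.
#' @return updated state, with `marker_on` set.
#' @export
step_agent <- function(state, field, network, params = behavior_params(),
                       t = 0) {
  state <- exploratory_update(state, t, params)
  e <- state$exploratory_direction
  hd <- state$heading
  # sensor readings in world frame
  sens <- c(pi / 4, -pi / 4, 0, pi) + hd
  readings <- vapply(sens, function(th) {
    d <- params$sensor_range + 1
    for (step in seq(0.25, params$sensor_range, by = 0.25)) {
      p <- matrix(state$position + step * c(cos(th), sin(th)), 1)
      if (.domain_sd(network, p) <= 0) { d <- step; break }
    }
    proximity_reading(d, params)
  }, numeric(1))
  av_r <- avoidance_vector(readings)              # robot frame
  rot <- matrix(c(cos(hd), sin(hd), -sin(hd), cos(hd)), 2)
  av <- as.numeric(rot %*% av_r)
  tv <- c(0, 0)
  if (!is.null(field) && params$w_follow > 0) {
    lp <- state$position + params$photo_offset * c(cos(hd + pi / 2), sin(hd + pi / 2))
    rp <- state$position + params$photo_offset * c(cos(hd - pi / 2), sin(hd - pi / 2))
    il <- sample_field(field, lp, params$photo_radius)
    ir <- sample_field(field, rp, params$photo_radius)
    tv <- as.numeric(rot %*% trail_vector(il, ir))
  }
  v <- params$w_explore * e + params$w_avoid * av + params$w_follow * tv
  if (sqrt(sum(v^2)) > 1e-9) state$heading <- atan2(v[2], v[1])
  stepv <- params$speed * params$tick * c(cos(state$heading), sin(state$heading))
  cand <- state$position + stepv
  if (.domain_sd(network, matrix(cand, 1)) > 0) {
    state$position <- cand
  }                                                # else: blocked, stay
  ar <- network$nodes[network$nodes$kind != "bifurcation", ]
  in_area <- FALSE
  for (i in seq_len(nrow(ar))) {
    if (all(.in_hexagon(matrix(state$position, 1), c(ar$x[i], ar$y[i]),
                        network$area_diameter))) in_area <- TRUE
  }
  state$marker_on <- !in_area
  state
}

# shared plumbing: params list for the C++ core
.cpp_params <- function(params) {
  list(speed = params$speed, tick = params$tick,
       turn_half_deg = params$turn_half_deg,
       redirection_mean_s = params$redirection_mean_s,
       w_explore = params$w_explore, w_avoid = params$w_avoid,
       w_follow = params$w_follow, sensor_range = params$sensor_range,
       sigmoid_mid = params$sigmoid_mid, sigmoid_slope = params$sigmoid_slope,
       robot_radius = params$robot_radius, photo_offset = params$photo_offset,
       photo_radius = params$photo_radius, disc_diameter = params$disc_diameter,
       disc_intensity = params$disc_intensity, cap = params$cap,
       tau = params$tau, evap_period = params$evap_period,
       deposit_period = params$deposit_period)
}

#' Simulate a swarm in the corridor network
#'
#' Full closed loop: agents start inside the start area, move by the
#' behavioural model, lay pheromone discs (marker off inside areas, ~5 Hz
#' deposition with the consecutive-disc non-overlap rule), and the raster
#' evaporates exponentially every 5 s. Per-second per-segment intensity
#' totals are recorded for the analysis pipeline.
#'
#' @param network a [build_network()] object.
#' @param n_agents number of agents.
#' @param duration seconds of simulated time.
#' @param params a [behavior_params()].
#' @param seed integer seed (reproducible).
#' @param record_dt trajectory sampling period, s (0 = no trajectory).
#' @param raster_shape pheromone raster `c(nx, ny)`.
#' @param pheromone if FALSE, no deposition/following (null model).
#' @param return_field if TRUE, include the final raster as a
#'   [pheromone_field()].
#' @return list of class `arena_sim`: `trajectory` (data.frame t, agent, x, y,
#'   heading, marker), `usage` (nseg x seconds matrix of per-segment totals),
#'   `trips`, `network`, and optionally `field`.
#' @export
simulate_arena <- function(network, n_agents = 10, duration = 3600,
                           params = behavior_params(), seed = 1,
                           record_dt = 0.2, raster_shape = c(800L, 600L),
                           pheromone = TRUE, return_field = FALSE) {
  stopifnot(inherits(network, "trail_network"), n_agents >= 0, duration >= 0)
  masks <- segment_masks(network, raster_shape)
  ar <- network$nodes[network$nodes$kind != "bifurcation", ]
  hexes <- as.matrix(ar[match(c("S", "T"), ar$id), c("x", "y")])
  if (n_agents == 0 || duration == 0) {
    emptytraj <- data.frame(t = numeric(0), agent = integer(0), x = numeric(0),
                            y = numeric(0), heading = numeric(0), marker = integer(0))
    out <- list(trajectory = emptytraj,
                usage = matrix(0, nrow(network$segments), max(1, floor(duration) + 1),
                               dimnames = list(network$segments$id, NULL)),
                trips = 0L, network = network)
    if (return_field) out$field <- pheromone_field(raster_shape[1], raster_shape[2],
                                                   network$extent)
    class(out) <- "arena_sim"
    return(out)
  }
  res <- .arena_run_cpp(network$polylines, hexes, network$area_diameter,
                        network$corridor_width / 2, network$extent,
                        masks$assignment, nrow(network$segments),
                        .cpp_params(params), as.integer(n_agents), duration,
                        record_dt, as.integer(seed) %% .Machine$integer.max,
                        pheromone, return_field)
  rownames(res$usage) <- network$segments$id
  out <- list(trajectory = res$trajectory, usage = res$usage,
              trips = res$trips, network = network)
  if (return_field) {
    f <- pheromone_field(raster_shape[1], raster_shape[2], network$extent)
    f$grid <- res$field
    out$field <- f
  }
  class(out) <- "arena_sim"
  out
}

#' @export
print.arena_sim <- function(x, ...) {
  cat(sprintf("<arena_sim> %s: %d trajectory samples, %d segments x %d s usage, %d round trips\n",
              x$network$config_label, nrow(x$trajectory), nrow(x$usage),
              ncol(x$usage), x$trips))
  invisible(x)
}

#' Single-agent branch-choice assay in an isolated Y-corridor
#'
#' Builds a Y of 9 cm corridors whose two branches deviate by the given angles
#' from the entry direction (opposite sides), releases one agent per trial at
#' the entry with no pheromone, and records which branch it enters first.
#' This isolates the interaction of the correlated random walk and wall
#' avoidance with the bifurcation geometry.
#'
#' @param deviations `c(dev1, dev2)` in degrees; the first branch deviates
#'   `dev1` to the left, the second `dev2` to the right.
#' @param n_trials number of independent single-agent trials.
#' @param params a [behavior_params()].
#' @param seed integer seed.
#' @param arm_length corridor arm length, cm.
#' @param max_trial_s per-trial time limit (unfinished trials are excluded).
#' @param entry_length approach corridor length, cm.
#' @param choice_dist distance past the junction at which the entered branch
#'   is recorded, cm.
#' @param heading_spread half-range (degrees) of the uniform heading
#'   perturbation applied at release, mimicking the imperfect alignment of
#'   arrivals from the curved corridors of the maze.
#' @return list of class `choice_assay`: `n1`, `n2` (branch entry counts),
#'   `timeouts`, `proportion` (first branch), `ci` (95% binomial), `test`
#'   (binom.test vs 0.5).
#' @export
bifurcation_choice_assay <- function(deviations = c(30, 120), n_trials = 1000,
                                     params = behavior_params(), seed = 1,
                                     arm_length = 40, max_trial_s = 240,
                                     entry_length = 25, choice_dist = 12,
                                     heading_spread = 65) {
  stopifnot(length(deviations) == 2L, all(deviations > 0), n_trials >= 1)
  jx <- entry_length + 15; jy <- 60
  entry <- rbind(c(15, jy), c(jx, jy))
  a1 <- deviations[1] * pi / 180
  a2 <- -deviations[2] * pi / 180
  b1 <- rbind(c(jx, jy), c(jx + arm_length * cos(a1), jy + arm_length * sin(a1)))
  b2 <- rbind(c(jx, jy), c(jx + arm_length * cos(a2), jy + arm_length * sin(a2)))
  polys <- list(entry = entry, branch1 = b1, branch2 = b2)
  xs <- unlist(lapply(polys, function(p) p[, 1]))
  ys <- unlist(lapply(polys, function(p) p[, 2]))
  extent <- c(min(xs) - 10, max(xs) + 10, min(ys) - 10, max(ys) + 10)
  res <- .arena_assay_cpp(polys, 4.5, extent, c(jx, jy),
                          list(b1[2, , drop = FALSE], b2[2, , drop = FALSE]),
                          .cpp_params(params), as.integer(n_trials), max_trial_s,
                          as.integer(seed) %% .Machine$integer.max, choice_dist,
                          heading_spread * pi / 180)
  n1 <- res$choose_first; n2 <- res$choose_second
  bt <- stats::binom.test(n1, n1 + n2, p = 0.5)
  out <- list(n1 = n1, n2 = n2, timeouts = res$timeouts,
              proportion = n1 / (n1 + n2),
              ci = as.numeric(bt$conf.int), test = bt,
              deviations = deviations)
  class(out) <- "choice_assay"
  out
}

#' @export
print.choice_assay <- function(x, ...) {
  cat(sprintf("<choice_assay> %g/%g deg Y-corridor: %d/%d = %.1f%% first branch (95%% CI %.1f-%.1f%%), %d timeouts\n",
              x$deviations[1], x$deviations[2], x$n1, x$n1 + x$n2,
              100 * x$proportion, 100 * x$ci[1], 100 * x$ci[2], x$timeouts))
  invisible(x)
}
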