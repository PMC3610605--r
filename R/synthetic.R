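# Synthetic data generators: scripted and random-walk trajectory logs and
# canned pheromone fields with known ground truth, so every pipeline stage is
# testable without hardware.

# arc-length parametrization of a chain of polylines (list of matrices)
.path_polyline <- function(network, segment_ids) {
  segs <- network$segments
  node <- "S"
  pts <- NULL
  for (s in segment_ids) {
    r <- segs[segs$id == s, ]
    p <- network$polylines[[s]]
    if (r$node_a != node) {
      p <- p[nrow(p):1, , drop = FALSE]
      node <- r$node_a
    } else {
      node <- r$node_b
    }
    pts <- if (is.null(pts)) p else rbind(pts, p[-1, , drop = FALSE])
  }
  pts
}

.interp_along <- function(pts, s) {
  seglen <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= nrow(pts)] <- nrow(pts) - 1L
  f <- (s - cum[i]) / pmax(seglen[i], 1e-12)
  cbind(pts[i, 1] + f * (pts[i + 1, 1] - pts[i, 1]),
        pts[i, 2] + f * (pts[i + 1, 2] - pts[i, 2]))
}

#' Scripted shuttle trajectories along designated paths
#'
#' Agents shuttle start -> target -> start along a given path at constant
#' speed, with smooth lateral jitter (AR(1) Gaussian) and dwell pauses inside
#' the areas; the trail marker follows the areas-off discipline. Ground truth
#' (the scripted path) is attached as an attribute.
#'
#' @param network a [build_network()] object.
#' @param specs list of per-agent specs: each a list with `path` (segment id
#'   vector), and optional `speed` (cm/s, default 4), `jitter_sd` (cm, default
#'   0.5), `dwell_s` (default 5).
#' @param duration seconds.
#' @param seed integer seed.
#' @param dt sampling period, s.
#' @return data.frame of class `trajectory_log` (t, agent, x, y, heading,
#'   marker) with attribute `ground_truth` (list of path ids per agent).
#' @export
scripted_trajectories <- function(network, specs, duration, seed = 1,
                                  dt = 0.2) {
  stopifnot(inherits(network, "trail_network"), length(specs) >= 1)
  set.seed(seed)
  ar <- network$nodes[network$nodes$kind != "bifurcation", ]
  out <- list()
  for (a in seq_along(specs)) {
    sp <- specs[[a]]
    speed <- if (is.null(sp$speed)) 4 else sp$speed
    jsd <- if (is.null(sp$jitter_sd)) 0.5 else sp$jitter_sd
    dwell <- if (is.null(sp$dwell_s)) 5 else sp$dwell_s
    pts <- .path_polyline(network, sp$path)
    total <- sum(sqrt(rowSums(diff(pts)^2)))
    tt <- seq(0, duration, by = dt)
    # position along a ping-pong schedule with dwells at both ends
    period <- 2 * (total / speed + dwell)
    tm <- tt %% period
    leg <- total / speed
    s <- ifelse(tm < leg, tm * speed,
         ifelse(tm < leg + dwell, total,
         ifelse(tm < 2 * leg + dwell, total - (tm - leg - dwell) * speed, 0)))
    base <- .interp_along(pts, s)
    # smooth lateral jitter: AR(1) with stationary sd jsd
    rho <- 0.95
    innov <- stats::rnorm(length(tt), 0, jsd * sqrt(1 - rho^2))
    j <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    eps <- 1e-3
    ahead <- .interp_along(pts, s + eps)
    dir <- ahead - base
    nrm <- sqrt(rowSums(dir^2)); nrm[nrm < 1e-12] <- 1
    normal <- cbind(-dir[, 2], dir[, 1]) / nrm
    xy <- base + normal * j
    # containment guard: fall back to the centerline where jitter would exit
    sd <- .domain_sd(network, xy)
    bad <- sd <= 0.2
    xy[bad, ] <- base[bad, ]
    heading <- atan2(dir[, 2], dir[, 1])
    marker <- rep(TRUE, length(tt))
    for (i in seq_len(nrow(ar))) {
      marker <- marker & !.in_hexagon(xy, c(ar$x[i], ar$y[i]),
                                      network$area_diameter)
    }
    out[[a]] <- data.frame(t = tt, agent = a, x = xy[, 1], y = xy[, 2],
                           heading = heading, marker = as.integer(marker))
  }
  log <- do.call(rbind, out)
  log <- log[order(log$t, log$agent), ]
  rownames(log) <- NULL
  attr(log, "ground_truth") <- lapply(specs, function(sp) sp$path)
  class(log) <- c("trajectory_log", "data.frame")
  log
}

#' Correlated-random-walk trajectories with no trail coupling
#'
#' Null-model generator: agents move by the behavioural model with trail
#' following and deposition disabled (exploration + wall avoidance only).
#'
#' @param network a [build_network()] object.
#' @param n_agents number of agents.
#' @param duration seconds.
#' @param seed integer seed.
#' @param params a [behavior_params()].
#' @param dt trajectory sampling period, s.
#' @return a `trajectory_log` data.frame.
#' @export
random_walk_trajectories <- function(network, n_agents, duration, seed = 1,
                                     params = behavior_params(), dt = 0.2) {
  if (n_agents == 0 || duration == 0) {
    log <- data.frame(t = numeric(0), agent = integer(0), x = numeric(0),
                      y = numeric(0), heading = numeric(0), marker = integer(0))
    class(log) <- c("trajectory_log", "data.frame")
    return(log)
  }
  sim <- simulate_arena(network, n_agents = n_agents, duration = duration,
                        params = params, seed = seed, record_dt = dt,
                        raster_shape = c(400L, 300L), pheromone = FALSE)
  log <- sim$trajectory
  class(log) <- c("trajectory_log", "data.frame")
  log
}

#' Paint a field with exact per-segment totals
#'
#' Spreads the requested total uniformly over each named segment's mask cells,
#' giving hand-traceable snapshots for the classifier.
#'
#' @param network a [build_network()] object.
#' @param levels named numeric vector: per-segment total intensity.
#' @param masks optional precomputed [segment_masks()].
#' @param raster_shape raster `c(nx, ny)`.
#' @return a float-mode [pheromone_field()].
#' @export
canned_field <- function(network, levels, masks = NULL,
                         raster_shape = c(800L, 600L)) {
  stopifnot(inherits(network, "trail_network"), all(levels >= 0))
  if (is.null(masks)) masks <- segment_masks(network, raster_shape)
  f <- pheromone_field(raster_shape[1], raster_shape[2], network$extent)
  for (s in names(levels)) {
    idx <- masks$masks[[s]]
    if (is.null(idx)) stop("unknown segment id: ", s)
    if (length(idx) == 0L) stop("segment ", s, " has no raster cells")
    v <- levels[[s]] / length(idx)
    if (v > 255) stop("requested level unreachable under the 255 cap for ", s)
    f$grid[idx] <- v
  }
  f
}

#' Write / read a trajectory log as CSV
#' @param log a `trajectory_log`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log)[, c("t", "agent", "x", "y", "heading",
                                          "marker")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  log <- utils::read.csv(path)
  class(log) <- c("trajectory_log", "data.frame")
  log
}

#' Rasterize a trajectory log into a pheromone field
#'
#' Replays deposition along recorded marker-on trajectories at the tracking
#' rate, applying the consecutive-disc non-overlap rule and the 5 s
#' evaporation schedule. This is the bridge from trajectory CSVs to fields
#' for the analysis pipeline.
#'
#' @param log a `trajectory_log` (t, agent, x, y, marker), ~5 Hz or denser.
#' @param field a [pheromone_field()] to start from.
#' @param snapshot_every if > 0, also return per-segment totals every that
#'   many seconds (requires `masks`).
#' @param masks a [segment_masks()] result (for snapshots).
#' @return list: `field` (final), and `usage` matrix if snapshots requested.
#' @export
field_from_trajectories <- function(log, field = NULL, snapshot_every = 1,
                                    masks = NULL) {
  if (is.null(field)) field <- pheromone_field()
  tt <- sort(unique(log$t))
  nseg <- if (!is.null(masks)) length(masks$masks) else 0L
  usage <- NULL
  snap_times <- NULL
  if (snapshot_every > 0 && !is.null(masks)) {
    snap_times <- seq(0, max(tt), by = snapshot_every)
    usage <- matrix(0, nseg, length(snap_times),
                    dimnames = list(names(masks$masks), NULL))
  }
  last_evap <- 0
  si <- 1L
  for (ti in tt) {
    while (ti - last_evap >= field$evap_period) {
      field <- evaporate(field)
      last_evap <- last_evap + field$evap_period
    }
    rows <- which(log$t == ti & log$marker > 0)
    for (r in rows) {
      field <- deposit(field, log$agent[r], c(log$x[r], log$y[r]))
    }
    if (!is.null(usage)) {
      while (si <= length(snap_times) && snap_times[si] <= ti) {
        usage[, si] <- vapply(masks$masks, function(idx) sum(field$grid[idx]),
                              numeric(1))
        si <- si + 1L
      }
    }
  }
  list(field = field, usage = usage)
}
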