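# Discrete stochastic model of agents traversing the segment graph with
# pheromone-dependent, geometry-biased branch choices.

#' Parameters of the discrete network model
#'
#' Time advances in 1 s steps. Agents inside the start/target areas leave with
#' probability `p_leave` per second; traversing segment i takes
#' `round(length_i / speed)` seconds; on entering a segment an agent marks it
#' with `Q` pheromone units per second of traversal (`Q * length_i / speed`
#' in total, mirroring the disc-per-distance trail laying of the raster
#' system); every step all segment pheromone decays by `exp(-1/tau)`. Branch
#' choices follow [choice_symmetric()] / [choice_asymmetric()] according to
#' the bifurcation's branch-angle annotation. Exit corridors from the areas
#' are drawn uniformly (agents random-walk inside areas with no pheromone).
#'
#' Defaults for `Q` and `p_leave` are the values fitted by
#' [calibrate_network_model()] against the four-condition foraging-efficiency
#' ratios; `k`, `n`, `alpha` defaults live in [choice_params()].
#'
#' @param speed agent speed, cm/s.
#' @param Q pheromone deposition rate per second of segment traversal
#'   (ignored when `pheromone_on` is FALSE).
#' @param tau evaporation characteristic time, s.
#' @param p_leave per-second probability of leaving an area.
#' @param C_cap per-segment pheromone saturation (the discrete counterpart of
#'   the projected raster's 255-per-cell cap): accumulation stops at this
#'   quantity, so heavily marked loops never become absorbing.
#' @param n_agents agents per run.
#' @param duration run length, s.
#' @param pheromone_on toggle deposition (Q is 0 exactly when FALSE).
#' @return list of class `network_model_params`.
#' @export
network_model_params <- function(speed = 4, Q = 0.12, tau = 1800,
                                 p_leave = 0.15, C_cap = 80,
                                 n_agents = 10,
                                 duration = 3600, pheromone_on = TRUE) {
  stopifnot(speed > 0, Q >= 0, tau > 0, p_leave > 0, p_leave <= 1,
            C_cap > 0, n_agents >= 1, duration >= 1)
  p <- as.list(environment())
  if (!p$pheromone_on) p$Q <- 0
  class(p) <- "network_model_params"
  p
}

# Build the integer tables the C++ stepper needs. Decision options are derived
# from the network's branch-angle annotations: a (node, incoming) whose two
# outgoing deviations are 30/120 gets the asymmetric operator with the 30-deg
# branch as "direct"; equal deviations (60/60 or 30/30) are symmetric.
.network_tables <- function(network) {
  segs <- network$segments
  nodes <- network$nodes$id
  nidx <- function(n) match(n, nodes) - 1L
  sidx <- function(s) match(s, segs$id) - 1L
  opts <- list()
  ba <- network$branch_angles
  for (n in setdiff(nodes, c("S", "T"))) {
    inc <- segs$id[segs$node_a == n | segs$node_b == n]
    for (si in inc) {
      others <- setdiff(inc, si)
      stopifnot(length(others) == 2L)
      d1 <- ba$deviation_deg[ba$node == n & ba$incoming == si & ba$outgoing == others[1]]
      d2 <- ba$deviation_deg[ba$node == n & ba$incoming == si & ba$outgoing == others[2]]
      direct <- 0L
      if (abs(d1 - d2) > 1) direct <- if (d1 < d2) 1L else 2L
      opts[[length(opts) + 1L]] <- c(nidx(n), sidx(si), sidx(others[1]),
                                     sidx(others[2]), direct)
    }
  }
  for (n in c("S", "T")) {
    inc <- segs$id[segs$node_a == n | segs$node_b == n]
    row <- c(nidx(n), -1L, sidx(inc[1]),
             if (length(inc) > 1L) sidx(inc[2]) else -1L, 0L)
    opts[[length(opts) + 1L]] <- row
  }
  list(options = do.call(rbind, opts),
       seg_from = vapply(segs$node_a, nidx, integer(1)),
       seg_to = vapply(segs$node_b, nidx, integer(1)),
       n_nodes = length(nodes),
       start = nidx("S"), target = nidx("T"))
}

#' Transit time of a path at constant speed
#'
#' Closed form `sum(length_i) / speed` for the listed segments.
#' @param network a [build_network()] object.
#' @param segment_ids character vector of segment ids.
#' @param speed cm/s.
#' @return time in seconds.
#' @export
transit_time <- function(network, segment_ids, speed = 4) {
  stopifnot(inherits(network, "trail_network"))
  sum(network$segments$length_cm[match(segment_ids, network$segments$id)]) / speed
}

#' Run the discrete network model
#'
#' @param network a [build_network()] object (its branch-angle annotations
#'   decide which choice operator applies at each bifurcation side).
#' @param params a [network_model_params()].
#' @param cparams a [choice_params()].
#' @param seed integer seed; identical seeds give identical logs.
#' @param n_runs number of independent runs.
#' @param trace if TRUE (and the first run), keep the per-agent event trace.
#' @param C_init optional named initial per-segment pheromone quantities.
#' @param freeze_field if TRUE the field is held fixed (no deposition or
#'   decay); useful for probing the response to a prescribed trail.
#' @return list of class `trip_log`: `trips` (integer vector, one per run),
#'   `first_choice` (counts of first segment chosen when leaving the start
#'   area), and `trace` (data.frame t, agent, segment, from_node) if requested.
#' @export
simulate_network <- function(network, params = network_model_params(),
                             cparams = choice_params(), seed = 1,
                             n_runs = 1, trace = n_runs == 1,
                             C_init = NULL, freeze_field = FALSE) {
  stopifnot(inherits(network, "trail_network"))
  if (is.null(C_init)) C_init <- numeric(nrow(network$segments))
  if (!is.null(names(C_init))) C_init <- C_init[network$segments$id]
  tb <- .network_tables(network)
  transit <- as.integer(round(network$segments$length_cm / params$speed))
  transit[transit < 1L] <- 1L
  Q <- if (params$pheromone_on) params$Q else 0
  res <- .network_sim_cpp(tb$n_nodes, tb$seg_from, tb$seg_to, transit,
                          tb$options, tb$start, tb$target,
                          cparams$k, cparams$n, cparams$alpha,
                          Q, params$tau, params$p_leave, params$C_cap,
                          as.integer(params$n_agents),
                          as.integer(params$duration),
                          as.integer(n_runs),
                          as.integer(seed) %% .Machine$integer.max, trace,
                          C_init, freeze_field)
  names(res$first_choice) <- network$segments$id
  out <- list(trips = as.integer(res$trips), first_choice = res$first_choice)
  if (trace) {
    tr <- res$trace
    tr$segment <- network$segments$id[tr$segment]
    tr$from_node <- network$nodes$id[tr$from_node]
    out$trace <- tr
  }
  out$config <- network$config_label
  class(out) <- "trip_log"
  out
}

#' @export
print.trip_log <- function(x, ...) {
  cat(sprintf("<trip_log> configuration %s: %d run(s), median %g successful trips\n",
              x$config, length(x$trips), stats::median(x$trips)))
  invisible(x)
}

#' Four-condition foraging-efficiency experiment
#'
#' Runs the network model under configuration S and A, each with and without
#' pheromone deposition, and summarizes the distributions of successful trips
#' (an agent returning to the start area after visiting the target area).
#'
#' @param network_S,network_A networks from [build_network()].
#' @param n_runs runs per condition.
#' @param params a [network_model_params()]; `pheromone_on` is overridden
#'   per condition.
#' @param cparams a [choice_params()].
#' @param seed integer seed.
#' @return list of class `condition_summary`: `trips` (named list of integer
#'   vectors for S-P, A-P, S+P, A+P), `medians`, `ratios` (A-P/S-P, S+P/S-P,
#'   A+P/A-P, A+P/S+P), and `tests` (two-sided Wilcoxon rank-sum comparisons).
#' @export
run_conditions <- function(network_S, network_A, n_runs = 1000,
                           params = network_model_params(),
                           cparams = choice_params(), seed = 1) {
  conds <- list(
    `S-P` = list(net = network_S, ph = FALSE),
    `A-P` = list(net = network_A, ph = FALSE),
    `S+P` = list(net = network_S, ph = TRUE),
    `A+P` = list(net = network_A, ph = TRUE))
  trips <- list()
  for (i in seq_along(conds)) {
    p <- params
    p$pheromone_on <- conds[[i]]$ph
    if (!p$pheromone_on) p$Q <- 0
    trips[[names(conds)[i]]] <- simulate_network(conds[[i]]$net, p, cparams,
                                                 seed = seed + 1000L * i,
                                                 n_runs = n_runs,
                                                 trace = FALSE)$trips
  }
  med <- vapply(trips, stats::median, numeric(1))
  ratios <- c(`A-P/S-P` = unname(med["A-P"] / med["S-P"]),
              `S+P/S-P` = unname(med["S+P"] / med["S-P"]),
              `A+P/A-P` = unname(med["A+P"] / med["A-P"]),
              `A+P/S+P` = unname(med["A+P"] / med["S+P"]))
  tests <- list(
    geometry_noP = stats::wilcox.test(trips[["A-P"]], trips[["S-P"]], exact = FALSE),
    pheromone_S = stats::wilcox.test(trips[["S+P"]], trips[["S-P"]], exact = FALSE),
    pheromone_A = stats::wilcox.test(trips[["A+P"]], trips[["A-P"]], exact = FALSE),
    geometry_P = stats::wilcox.test(trips[["A+P"]], trips[["S+P"]], exact = FALSE))
  out <- list(trips = trips, medians = med, ratios = ratios, tests = tests,
              n_runs = n_runs)
  class(out) <- "condition_summary"
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %d runs per condition\n", x$n_runs))
  cat("  medians:", paste(names(x$medians), round(x$medians, 1),
                          sep = "=", collapse = "  "), "\n")
  cat("  ratios :", paste(names(x$ratios), round(x$ratios, 3),
                          sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Calibrate the network model against median-trip ratios
#'
#' Random + local search over the free parameters minimizing the squared
#' log-ratio error against the four target median ratios. Runs a reduced
#' number of Monte-Carlo replicates per evaluation, so the result carries
#' Monte-Carlo noise; the fitted values are persisted as the package defaults
#' in [network_model_params()] / [choice_params()].
#'
#' @param network_S,network_A networks from [build_network()].
#' @param targets the four median ratios, ordered A-P/S-P, S+P/S-P, A+P/A-P,
#'   A+P/S+P; an empty/NULL target list returns the starting parameters
#'   unchanged.
#' @param free named list of starting values for the free parameters (subset
#'   of k, n, Q, p_leave; alpha is fixed by the unmarked 2/3 direct-branch
#'   choice).
#' @param budget number of candidate evaluations.
#' @param n_runs Monte-Carlo runs per condition per evaluation.
#' @param tol acceptable root-mean-square log-ratio error.
#' @param seed integer seed.
#' @return list of class `network_calibration`: `params`, `cparams`,
#'   `achieved` ratios, `rmse`, `converged` flag, and the evaluation `history`.
#' @export
calibrate_network_model <- function(network_S, network_A,
                                    targets = c(1.05, 1.30, 1.80, 1.46),
                                    free = list(k = 9, n = 2.5, Q = 0.12,
                                                p_leave = 0.15),
                                    budget = 40, n_runs = 120, tol = 0.05,
                                    seed = 1) {
  if (is.null(targets) || length(targets) == 0L) {
    out <- list(params = do.call(network_model_params,
                                 free[intersect(names(free), c("Q", "p_leave"))]),
                cparams = do.call(choice_params,
                                  free[intersect(names(free), c("k", "n"))]),
                achieved = NULL, rmse = NA_real_, converged = TRUE,
                history = data.frame())
    class(out) <- "network_calibration"
    return(out)
  }
  stopifnot(length(targets) == 4L, all(targets > 0))
  lt <- log(targets)
  evalp <- function(fr, s) {
    pp <- network_model_params(Q = fr$Q, p_leave = fr$p_leave)
    cp <- choice_params(k = fr$k, n = fr$n)
    cs <- run_conditions(network_S, network_A, n_runs = n_runs, params = pp,
                         cparams = cp, seed = s)
    sqrt(mean((log(cs$ratios) - lt)^2))
  }
  set.seed(seed)
  cur <- free
  best <- list(fr = cur, rmse = evalp(cur, seed))
  hist <- list(data.frame(k = cur$k, n = cur$n, Q = cur$Q,
                          p_leave = cur$p_leave, rmse = best$rmse))
  for (i in seq_len(budget - 1L)) {
    cand <- best$fr
    # log-scale random perturbations, shrinking over the budget
    sc <- 0.5 * (1 - i / budget) + 0.08
    cand$k <- max(0.5, cand$k * exp(stats::rnorm(1, 0, sc)))
    cand$n <- min(4, max(1, cand$n * exp(stats::rnorm(1, 0, sc / 2))))
    cand$Q <- max(0.1, cand$Q * exp(stats::rnorm(1, 0, sc)))
    cand$p_leave <- min(0.5, max(0.005, cand$p_leave * exp(stats::rnorm(1, 0, sc))))
    r <- evalp(cand, seed + i)
    hist[[length(hist) + 1L]] <- data.frame(k = cand$k, n = cand$n, Q = cand$Q,
                                            p_leave = cand$p_leave, rmse = r)
    if (r < best$rmse) best <- list(fr = cand, rmse = r)
    if (best$rmse < tol) break
  }
  pp <- network_model_params(Q = best$fr$Q, p_leave = best$fr$p_leave)
  cp <- choice_params(k = best$fr$k, n = best$fr$n)
  cs <- run_conditions(network_S, network_A, n_runs = n_runs, params = pp,
                       cparams = cp, seed = seed + budget + 1L)
  out <- list(params = pp, cparams = cp, achieved = cs$ratios,
              rmse = best$rmse, converged = best$rmse < tol,
              history = do.call(rbind, hist))
  if (!out$converged) {
    warning("calibration budget exhausted before reaching tolerance; ",
            "returning best-found parameters")
  }
  class(out) <- "network_calibration"
  out
}

#' @export
print.network_calibration <- function(x, ...) {
  cat("<network_calibration>\n")
  cat(sprintf("  k=%.3g n=%.3g Q=%.3g p_leave=%.3g (rmse %.3f, %s)\n",
              x$cparams$k, x$cparams$n, x$params$Q, x$params$p_leave,
              x$rmse, if (x$converged) "converged" else "budget exhausted"))
  if (!is.null(x$achieved)) {
    cat("  achieved ratios:", paste(names(x$achieved), round(x$achieved, 3),
                                    sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}
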