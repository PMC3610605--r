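# Selection-event segmentation and the statistics suite of the analysis
# pipeline. A selection event is a maximal run of consecutive seconds during
# which the collective path classification stays in one category.

#' Run-length encode a path-category series into selection events
#'
#' @param categories character (or factor) vector of per-second path
#'   categories, e.g. `"4"`, `"6"`, `"8"`, `"10"`, `"LOOP"`, `"NONE"`.
#' @param times optional vector of times (s) aligned with `categories`;
#'   defaults to `0, 1, 2, ...`. Must be a regular 1 Hz grid.
#' @return a data.frame with columns `category`, `start` (s), `duration` (s).
#'   Events tile the timeline without overlap; adjacent events always have
#'   different categories.
#' @export
selection_events <- function(categories, times = NULL) {
  categories <- as.character(categories)
  n <- length(categories)
  if (n == 0L) {
    return(data.frame(category = character(0), start = numeric(0),
                      duration = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.null(times)) times <- seq_len(n) - 1
  stopifnot(length(times) == n)
  if (n > 1L) {
    dt <- diff(times)
    if (any(abs(dt - dt[1]) > 1e-9)) stop("category series must be regularly sampled")
    step <- dt[1]
  } else {
    step <- 1
  }
  r <- rle(categories)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(category = r$values,
             start = times[starts],
             duration = r$lengths * step,
             stringsAsFactors = FALSE)
}

#' Per-replicate selection-event summary
#'
#' @param events data.frame from [selection_events()].
#' @return list with `n_events` and a data.frame `by_category` of mean event
#'   duration and count per category.
#' @export
summarize_events <- function(events) {
  stopifnot(all(c("category", "duration") %in% names(events)))
  by_cat <- aggregate(duration ~ category, data = events,
                      FUN = function(d) c(mean = mean(d), n = length(d)))
  out <- data.frame(category = by_cat$category,
                    mean_duration = by_cat$duration[, "mean"],
                    n = by_cat$duration[, "n"],
                    stringsAsFactors = FALSE)
  list(n_events = nrow(events), by_category = out)
}

#' Statistics suite of the analysis pipeline
#'
#' Bundles the tests used to compare individual branch choices and collective
#' selection dynamics: a chi-squared goodness-of-fit test of choice counts
#' against an unbiased 1/2 split, a two-sided Fisher exact test comparing two
#' groups' choice counts, a one-sided two-sample Wilcoxon rank-sum test with
#' continuity correction on per-replicate event counts, and a two-way ANOVA
#' (category x configuration) on event durations with Tukey HSD pairwise
#' comparisons.
#'
#' @param choice_counts optional numeric `c(direct, wide)` counts for the
#'   goodness-of-fit test.
#' @param choice_table optional 2x2 matrix of counts (rows = groups,
#'   columns = direct/wide) for the Fisher exact test.
#' @param event_counts optional data.frame with columns `config` and `n_events`
#'   (one row per replicate); tests whether counts in the first configuration
#'   level are greater than in the second.
#' @param durations optional data.frame with columns `category`, `config`,
#'   `duration` for the two-way ANOVA; needs at least two replicates per cell.
#' @return list of htest / aov results, with elements `chisq`, `fisher`,
#'   `wilcoxon`, `anova`, `tukey` for the supplied inputs.
#' @export
stats_suite <- function(choice_counts = NULL, choice_table = NULL,
                        event_counts = NULL, durations = NULL) {
  out <- list()
  if (!is.null(choice_counts)) {
    stopifnot(length(choice_counts) == 2L, all(choice_counts >= 0))
    out$chisq <- stats::chisq.test(choice_counts, p = c(0.5, 0.5))
  }
  if (!is.null(choice_table)) {
    choice_table <- as.matrix(choice_table)
    stopifnot(all(dim(choice_table) == c(2L, 2L)))
    out$fisher <- stats::fisher.test(choice_table, alternative = "two.sided")
  }
  if (!is.null(event_counts)) {
    stopifnot(all(c("config", "n_events") %in% names(event_counts)))
    cfg <- factor(event_counts$config)
    if (nlevels(cfg) != 2L) stop("event_counts must have exactly two configurations")
    lv <- levels(cfg)
    out$wilcoxon <- stats::wilcox.test(
      event_counts$n_events[cfg == lv[1]],
      event_counts$n_events[cfg == lv[2]],
      alternative = "greater", correct = TRUE, exact = FALSE)
  }
  if (!is.null(durations)) {
    stopifnot(all(c("category", "config", "duration") %in% names(durations)))
    tab <- table(durations$category, durations$config)
    if (any(tab > 0 & tab < 2)) {
      stop("two-way ANOVA needs at least two replicates per non-empty cell")
    }
    durations$category <- factor(durations$category)
    durations$config <- factor(durations$config)
    fit <- stats::aov(duration ~ category + config, data = durations)
    out$anova <- fit
    out$tukey <- stats::TukeyHSD(fit)
  }
  out
}
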