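#' Per-trial scalar responses
#'
#' A trial's response is the mean signal over the stimulus window: frames
#' `onset .. onset + round(window_s * rate) - 1` (round half away from zero,
#' at least one frame). Trials whose window falls outside the trace are
#' flagged invalid (`NA` response).
#'
#' @param traces a `dff_traces` or `event_rates` object, or a numeric
#'   neuron x time matrix.
#' @param trial_table trial table with `condition`, `is_catch`,
#'   `onset_frame` and `run_speed` columns.
#' @param space the `stimulus_space` the `condition` column indexes.
#' @param window_s stimulus window length in seconds (default 1).
#' @param frame_rate_hz frame rate; taken from `traces` when available.
#' @param signal_kind `"dff"` or `"events"`; inferred when possible.
#' @return An object of class `"response_matrix"`: `values` (neuron x
#'   trial), `trial_table`, `space`, `inlier` (neuron x trial logical,
#'   initialized to valid trials), `state` (per-trial logical, initialized
#'   `TRUE`), `signal_kind`.
#' @export
trial_responses <- function(traces, trial_table, space, window_s = 1.0,
                            frame_rate_hz = NULL, signal_kind = NULL) {
  if (inherits(traces, "dff_traces")) {
    m <- traces$dff
    if (is.null(frame_rate_hz)) frame_rate_hz <- traces$frame_rate_hz
    if (is.null(signal_kind)) signal_kind <- "dff"
  } else if (inherits(traces, "event_rates")) {
    m <- traces$rates
    if (is.null(frame_rate_hz)) frame_rate_hz <- traces$frame_rate_hz
    if (is.null(signal_kind)) signal_kind <- "events"
  } else {
    m <- traces
    if (is.null(signal_kind)) signal_kind <- "dff"
  }
  if (is.null(frame_rate_hz)) stop("'frame_rate_hz' is required")
  w <- max(1L, round_half_up(window_s * frame_rate_hz))
  n_trials <- nrow(trial_table)
  values <- matrix(NA_real_, nrow(m), n_trials)
  valid <- logical(n_trials)
  for (tr in seq_len(n_trials)) {
    a <- trial_table$onset_frame[tr]
    b <- a + w - 1L
    if (a < 1 || b > ncol(m)) next
    valid[tr] <- TRUE
    values[, tr] <- rowMeans(m[, a:b, drop = FALSE])
  }
  if (!all(valid))
    warning(sprintf("%d trial(s) have stimulus windows outside the trace ",
                    sum(!valid)), "and were flagged invalid")
  response_matrix(values, trial_table, space, signal_kind = signal_kind,
                  inlier = matrix(rep(valid, each = nrow(m)), nrow(m)))
}

#' Construct a response matrix
#'
#' Container for neuron x trial scalar responses together with the trial
#' table, stimulus space, an inlier mask (neuron x trial) and a per-trial
#' behavioural-state mask.
#'
#' @param values neuron x trial numeric matrix.
#' @param trial_table trial table (`condition`, `is_catch`, `run_speed`, ...).
#' @param space a `stimulus_space`.
#' @param signal_kind `"dff"` or `"events"`.
#' @param inlier optional initial inlier mask.
#' @param state optional initial per-trial state mask.
#' @return an object of class `"response_matrix"`.
#' @export
response_matrix <- function(values, trial_table, space,
                            signal_kind = "dff", inlier = NULL,
                            state = NULL) {
  stopifnot(ncol(values) == nrow(trial_table),
            inherits(space, "stimulus_space"))
  if (is.null(inlier)) inlier <- matrix(TRUE, nrow(values), ncol(values))
  if (is.null(state)) state <- rep(TRUE, ncol(values))
  inlier <- inlier & !is.na(values)
  structure(list(values = values, trial_table = trial_table, space = space,
                 inlier = inlier, state = state, signal_kind = signal_kind),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix (%s): %d neurons x %d trials, %d in state\n",
              x$signal_kind, nrow(x$values), ncol(x$values), sum(x$state)))
  invisible(x)
}

#' Behavioural-state trial filter
#'
#' Running trials: mean run speed above `thresh` (default 10 cm/s).
#' Stationary trials: maximum absolute run speed below `thresh`
#' (default 1 cm/s); uses the `run_speed_max` column when present, else
#' `run_speed`.
#'
#' @param trial_table trial table with a `run_speed` column.
#' @param mode `"running"` or `"stationary"`.
#' @param thresh speed threshold in cm/s (default 10 for running, 1 for
#'   stationary).
#' @return logical per-trial flags.
#' @export
state_filter <- function(trial_table, mode = c("running", "stationary"),
                         thresh = NULL) {
  mode <- match.arg(mode)
  if (mode == "running") {
    if (is.null(thresh)) thresh <- 10
    flags <- trial_table$run_speed > thresh
  } else {
    if (is.null(thresh)) thresh <- 1
    speed <- if (!is.null(trial_table$run_speed_max))
      trial_table$run_speed_max else trial_table$run_speed
    flags <- abs(speed) < thresh
  }
  if (!any(flags))
    warning(sprintf("no trials pass the %s-state filter", mode))
  flags
}

#' Median-rule outlier flags
#'
#' A value is an inlier iff `|v - median| <= factor * IQR` (type-7
#' quantiles), with `factor = 2.3` by default. With fewer than 4 values all
#' are inliers (with a warning). A constant vector (IQR 0) has no outliers.
#'
#' @param values numeric vector.
#' @param factor multiple of the IQR (default 2.3).
#' @return logical inlier flags, same length as `values`.
#' @export
median_rule_outliers <- function(values, factor = 2.3) {
  ok <- is.finite(values)
  if (sum(ok) < 4) {
    if (sum(ok) > 0)
      warning("fewer than 4 values; all treated as inliers")
    return(ok)
  }
  med <- stats::median(values[ok])
  iqr <- stats::IQR(values[ok], type = 7)
  inl <- ok & abs(values - med) <= factor * iqr
  inl[!ok] <- FALSE
  inl
}

#' Apply running-state and median-rule filters to a response matrix
#'
#' Sets the per-trial state mask from [state_filter()], flags run-speed
#' outliers among in-state trials (median rule on speeds), then flags
#' response outliers independently per neuron x condition among the
#' remaining trials.
#'
#' @param resp a `response_matrix`.
#' @param mode,thresh passed to [state_filter()]; `mode = "none"` skips the
#'   state filter.
#' @param factor IQR multiple for the median rule.
#' @return the `response_matrix` with updated `state` and `inlier` masks.
#' @export
filter_responses <- function(resp, mode = "running", thresh = NULL,
                             factor = 2.3) {
  stopifnot(inherits(resp, "response_matrix"))
  tt <- resp$trial_table
  if (mode != "none") {
    state <- state_filter(tt, mode, thresh)
    sp_in <- suppressWarnings(
      median_rule_outliers(ifelse(state, tt$run_speed, NA_real_), factor))
    resp$state <- state & sp_in
  }
  for (i in seq_len(nrow(resp$values))) {
    for (c_id in unique(tt$condition)) {
      idx <- which(tt$condition == c_id & resp$state & resp$inlier[i, ])
      if (length(idx) == 0) next
      inl <- suppressWarnings(median_rule_outliers(resp$values[i, idx], factor))
      resp$inlier[i, idx] <- inl
    }
  }
  resp
}

#' Benjamini-Hochberg rejection flags
#'
#' Standard step-up false-discovery-rate procedure at level `alpha`
#' (via [stats::p.adjust()]).
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return logical rejection flags.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH") <= alpha
}

#' Responsiveness testing and neuron classification
#'
#' For every neuron and every non-catch condition, a Welch two-sample t-test
#' compares that condition's inlier in-state responses against all catch
#' responses. A condition is a significant response iff its raw mean
#' response is greater than 0 AND the test survives Benjamini-Hochberg
#' correction across the neuron's stimulus conditions. Conditions with fewer
#' than 2 testable trials get `p = 1` and are flagged untestable. Neurons
#' are then classified from their significant conditions
#' ([classify_neuron()]).
#'
#' @param resp a `response_matrix` (state/inlier masks applied first, e.g.
#'   via [filter_responses()]).
#' @param alpha FDR level (default 0.05).
#' @return An object of class `"significance_table"`: `p`, `significant`,
#'   `mean_response`, `untestable` (neuron x condition matrices over
#'   non-catch conditions), `responsive` and `class` (per neuron).
#' @export
responsiveness <- function(resp, alpha = 0.05) {
  stopifnot(inherits(resp, "response_matrix"))
  tt <- resp$trial_table
  space <- resp$space
  conds <- which(!space$is_catch)
  catch_id <- which(space$is_catch)
  if (length(catch_id) != 1) stop("response matrix must include catch trials")
  n <- nrow(resp$values)
  p <- mat <- matrix(NA_real_, n, length(conds))
  untestable <- matrix(FALSE, n, length(conds))
  for (i in seq_len(n)) {
    use <- resp$state & resp$inlier[i, ]
    catch_vals <- resp$values[i, tt$condition == catch_id & use]
    for (j in seq_along(conds)) {
      v <- resp$values[i, tt$condition == conds[j] & use]
      mat[i, j] <- mean(v)
      if (length(v) < 2 || length(catch_vals) < 2 ||
          (stats::sd(v) == 0 && stats::sd(catch_vals) == 0)) {
        p[i, j] <- 1
        untestable[i, j] <- TRUE
      } else {
        p[i, j] <- stats::t.test(v, catch_vals)$p.value
      }
    }
  }
  sig <- matrix(FALSE, n, length(conds))
  for (i in seq_len(n))
    sig[i, ] <- bh_adjust(p[i, ], alpha) & mat[i, ] > 0
  cls <- vapply(seq_len(n), function(i) classify_neuron(sig[i, ], space),
                character(1))
  structure(list(p = p, significant = sig, mean_response = mat,
                 untestable = untestable,
                 responsive = rowSums(sig) > 0, class = cls,
                 alpha = alpha, space = space),
            class = "significance_table")
}

#' Classify a neuron from its significant conditions
#'
#' `"single"`: significant response to exactly one single-element stimulus;
#' `"multi"`: to two or more single-element stimuli; `"combination"`: to no
#' single-element stimulus but at least one multi-element stimulus;
#' `"none"` otherwise.
#'
#' @param sig_flags logical vector over the non-catch conditions (canonical
#'   order).
#' @param space the `stimulus_space`.
#' @return one of `"single"`, `"multi"`, `"combination"`, `"none"`.
#' @export
classify_neuron <- function(sig_flags, space) {
  non_catch <- which(!space$is_catch)
  stopifnot(length(sig_flags) == length(non_catch))
  sizes <- space$size[non_catch]
  n_single <- sum(sig_flags & sizes == 1)
  n_multi <- sum(sig_flags & sizes >= 2)
  if (n_single == 1) "single"
  else if (n_single >= 2) "multi"
  else if (n_multi >= 1) "combination"
  else "none"
}

#' @export
print.significance_table <- function(x, ...) {
  cat(sprintf("Responsiveness: %d/%d neurons responsive\n",
              sum(x$responsive), length(x$responsive)))
  print(table(x$class))
  invisible(x)
}
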