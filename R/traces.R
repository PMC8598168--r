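#' Neuropil contamination coefficient of one ROI
#'
#' The contamination coefficient is defined by assuming (i) the true somatic
#' fluorescence can never be negative and (ii) the neuropil cannot
#' contaminate more than its measured value:
#' `k = min_t R(t) / N(t)`, clamped to 1 from above. The minimum is taken
#' over frames where `N(t) > eps`; a negative minimum (negative recorded
#' fluorescence) clamps to 0 with a warning.
#'
#' @param R_i ROI fluorescence time series.
#' @param N_i neuropil time series, same length.
#' @param eps guard below which neuropil frames are excluded (default 1e-9).
#' @return scalar k in `[0, 1]`.
#' @export
contamination_coefficient <- function(R_i, N_i, eps = 1e-9) {
  if (length(R_i) != length(N_i))
    stop("R and N time series must have the same length")
  valid <- is.finite(N_i) & N_i > eps & is.finite(R_i)
  if (!any(valid))
    stop("degenerate input: no frames with neuropil above eps")
  k <- min(R_i[valid] / N_i[valid])
  if (k < 0) {
    warning("negative min R/N ratio; clamping contamination coefficient to 0")
    k <- 0
  }
  min(k, 1)
}

#' Neuropil-correct a set of raw traces
#'
#' Subtracts the scaled neuropil channel from every ROI:
#' `F_i(t) = R_i(t) - k_i N_i(t)`, with `k_i` the per-ROI min-ratio
#' contamination coefficient ([contamination_coefficient()]). The min
#' construction guarantees `F_i(t) >= 0` on every frame with neuropil above
#' the guard. ROIs whose neuropil channel never exceeds the guard are
#' flagged degenerate and passed through uncorrected (`k = 0`), not dropped.
#'
#' @param raw a `raw_traces` object (fields `R`, `N`, `frame_rate_hz`).
#' @param eps neuropil guard (default 1e-9).
#' @return An object of class `"corrected_traces"`: `F` (neuron x time),
#'   `k` (per-neuron coefficients), `degenerate` (logical flags),
#'   `frame_rate_hz`.
#' @export
neuropil_correct <- function(raw, eps = 1e-9) {
  stopifnot(!is.null(raw$R), !is.null(raw$N),
            all(dim(raw$R) == dim(raw$N)))
  n <- nrow(raw$R)
  k <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    ki <- tryCatch(contamination_coefficient(raw$R[i, ], raw$N[i, ], eps),
                   error = function(e) NA_real_)
    if (is.na(ki)) {
      degenerate[i] <- TRUE
      k[i] <- 0
    } else k[i] <- ki
  }
  structure(list(F = raw$R - k * raw$N, k = k, degenerate = degenerate,
                 frame_rate_hz = raw$frame_rate_hz),
            class = "corrected_traces")
}

#' dF/F with a catch-trial ITI baseline
#'
#' Computes each neuron's baseline fluorescence `f0` by averaging its
#' corrected fluorescence over the last `window_s` seconds of the
#' inter-trial interval following each catch trial, then averaging across
#' catch trials; `dFF = (F - f0) / f0`. Neurons with `f0 <= 0` are flagged
#' invalid (their dF/F is set to `NA`).
#'
#' @param corrected a `corrected_traces` object (or any list with `F` and
#'   `frame_rate_hz`).
#' @param trial_table trial table with `is_catch` and `iti_end_frame`
#'   columns (frames 1-based; the post-trial ITI ends at `iti_end_frame`).
#' @param window_s baseline window length in seconds (default 1).
#' @return An object of class `"dff_traces"`: `dff` (neuron x time), `f0`
#'   (per neuron), `invalid` (logical), `scheme = "catch_iti"`,
#'   `frame_rate_hz`.
#' @export
dff_catch_baseline <- function(corrected, trial_table, window_s = 1.0) {
  Fm <- corrected$F
  rate <- corrected$frame_rate_hz
  catch <- which(trial_table$is_catch)
  if (length(catch) == 0) stop("no catch trials in trial table")
  w <- max(1L, round_half_up(window_s * rate))
  frames <- unlist(lapply(catch, function(tr) {
    end <- trial_table$iti_end_frame[tr]
    if (end > ncol(Fm)) return(integer(0))
    seq.int(end - w + 1L, end)
  }))
  if (length(frames) == 0) stop("no catch trial has a complete post-trial ITI")
  f0 <- rowMeans(Fm[, frames, drop = FALSE])
  invalid <- !is.finite(f0) | f0 <= 0
  dff <- (Fm - f0) / f0
  dff[invalid, ] <- NA_real_
  structure(list(dff = dff, f0 = f0, invalid = invalid,
                 scheme = "catch_iti", frame_rate_hz = rate),
            class = "dff_traces")
}

#' dF/F with a sliding-percentile baseline
#'
#' Per-frame baseline `f0(t)` is the windowed 20th percentile (type-7
#' quantile, centered window, truncated at the edges) of the corrected
#' trace; `dFF = (F - f0) / f0`. If the window exceeds the trace length a
#' single global percentile is used, with a warning. Intended for sessions
#' with short inter-stimulus intervals where no clean catch baseline exists.
#'
#' @param corrected a `corrected_traces` object.
#' @param window_frames sliding window width in frames (default 3000).
#' @param percentile baseline percentile (default 20).
#' @param stride stride (frames) at which the percentile is evaluated
#'   exactly; values between grid points are linearly interpolated.
#'   `stride = 1` (default) is the exact sliding percentile.
#' @return a `dff_traces` object with per-frame `f0` (neuron x time) and
#'   `scheme = "sliding_percentile"`.
#' @export
dff_percentile_baseline <- function(corrected, window_frames = 3000,
                                    percentile = 20, stride = 1L) {
  Fm <- corrected$F
  n_frames <- ncol(Fm)
  prob <- percentile / 100
  if (window_frames >= n_frames) {
    warning("percentile window exceeds trace length; using a global baseline")
    f0v <- apply(Fm, 1, stats::quantile, probs = prob, names = FALSE)
    f0 <- matrix(f0v, nrow(Fm), n_frames)
  } else {
    half <- floor(window_frames / 2)
    grid <- unique(c(seq(1L, n_frames, by = as.integer(stride)), n_frames))
    f0 <- matrix(NA_real_, nrow(Fm), n_frames)
    for (i in seq_len(nrow(Fm))) {
      qg <- vapply(grid, function(t0) {
        lo <- max(1L, t0 - half); hi <- min(n_frames, t0 + half)
        stats::quantile(Fm[i, lo:hi], probs = prob, names = FALSE)
      }, numeric(1))
      f0[i, ] <- if (length(grid) == n_frames) qg
                 else stats::approx(grid, qg, xout = seq_len(n_frames))$y
    }
  }
  invalid <- apply(f0, 1, function(r) any(!is.finite(r) | r <= 0))
  dff <- (Fm - f0) / f0
  dff[invalid, ] <- NA_real_
  structure(list(dff = dff, f0 = f0, invalid = invalid,
                 scheme = "sliding_percentile",
                 frame_rate_hz = corrected$frame_rate_hz),
            class = "dff_traces")
}

#' Sparse nonnegative deconvolution of dF/F traces
#'
#' Recovers a nonnegative event-rate series per neuron by solving
#' \deqn{\min_{e \ge 0} \; \|y - K e\|_2^2 + \lambda \|e\|_1,}
#' where `K` convolves with a unit-amplitude exponential kernel
#' `g^t`, `g = exp(-1 / (rate * tau))`. Solved by FISTA (proximal gradient
#' with Nesterov acceleration); the convolution and its adjoint are O(T)
#' recursive filters, so each iteration is linear in trace length. Output
#' rates are scaled such that an event train whose reconvolution has
#' time-averaged dF/F of 1 has time-averaged rate 1 (scale factor
#' `1 / (1 - g)`, the kernel sum).
#'
#' @param dff a `dff_traces` object, or a numeric matrix/vector of dF/F.
#' @param kernel_tau_s kernel decay time constant, seconds.
#' @param sparsity_weight L1 penalty weight `lambda` (default 0.02).
#' @param frame_rate_hz frame rate; taken from `dff` when available.
#' @param max_iter,tol FISTA iteration cap and relative-change tolerance.
#' @return An object of class `"event_rates"`: `rates` (neuron x time,
#'   nonnegative, normalized as above), `kernel_tau_s`, `frame_rate_hz`,
#'   `iterations` (per neuron), `converged` (logical per neuron).
#' @export
deconvolve <- function(dff, kernel_tau_s = 1.5, sparsity_weight = 0.02,
                       frame_rate_hz = NULL, max_iter = 1500, tol = 1e-8) {
  if (inherits(dff, "dff_traces")) {
    if (is.null(frame_rate_hz)) frame_rate_hz <- dff$frame_rate_hz
    y <- dff$dff
  } else y <- dff
  if (is.null(frame_rate_hz)) stop("'frame_rate_hz' is required")
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  stopifnot(kernel_tau_s > 0)
  g <- exp(-1 / (frame_rate_hz * kernel_tau_s))
  conv <- function(x) as.numeric(stats::filter(x, g, method = "recursive"))
  adj <- function(x) rev(as.numeric(stats::filter(rev(x), g,
                                                  method = "recursive")))
  L <- (1 / (1 - g))^2          # ||K||_2^2 upper bound (kernel l1 norm squared)
  lam <- sparsity_weight
  n <- nrow(y)
  rates <- matrix(0, n, ncol(y))
  iters <- integer(n)
  converged <- logical(n)
  for (i in seq_len(n)) {
    yi <- y[i, ]
    if (any(!is.finite(yi))) { rates[i, ] <- NA_real_; next }
    e <- numeric(length(yi)); z <- e; tk <- 1
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      gradz <- adj(conv(z) - yi)
      e_new <- pmax(z - (2 * gradz + lam) / (2 * L), 0)
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- e_new + ((tk - 1) / tk_new) * (e_new - e)
      e <- e_new; tk <- tk_new
      if (it %% 10 == 0) {
        obj <- sum((conv(e) - yi)^2) + lam * sum(e)
        if (is.finite(obj_prev) &&
            abs(obj_prev - obj) <= tol * max(1, abs(obj_prev))) {
          converged[i] <- TRUE; iters[i] <- it; break
        }
        obj_prev <- obj
      }
      iters[i] <- it
    }
    if (!converged[i] && iters[i] >= max_iter)
      warning(sprintf(paste0("deconvolution for neuron %d stopped at the ",
                             "iteration cap (%d) before reaching tolerance"),
                      i, max_iter))
    rates[i, ] <- e / (1 - g)
  }
  structure(list(rates = rates, kernel_tau_s = kernel_tau_s,
                 frame_rate_hz = frame_rate_hz, iterations = iters,
                 converged = converged),
            class = "event_rates")
}
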