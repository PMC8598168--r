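#' Configuration of a synthetic imaging session
#'
#' Collects the generative parameters of a synthetic session: population
#' size, stimulus space, trial structure (1 s stimulus, 2 s inter-trial
#' interval, 20 trials per condition including catch), calcium kinetics
#' (single-exponential GCaMP6s-like kernel), fluorescence baseline and
#' neuropil model, running-speed model, and the seed.
#'
#' @param n_neurons number of neurons.
#' @param n_elements number of stimulus elements (default 5).
#' @param trials_per_condition trials per condition, catch included
#'   (default 20).
#' @param stim_duration_s stimulus duration in seconds (default 1).
#' @param iti_s inter-trial interval in seconds (default 2).
#' @param frame_rate_hz imaging frame rate in Hz (default 15.45).
#' @param kernel_tau_s calcium kernel decay time constant, seconds
#'   (default 1.5, GCaMP6s-like).
#' @param baseline_f0 somatic baseline fluorescence, arbitrary units.
#' @param neuropil_sd white-noise SD of the neuropil channel.
#' @param neuropil_base mean level of the shared neuropil background.
#' @param neuropil_slow_amp amplitude of the slow shared background drift.
#' @param noise_frac per-neuron trial noise SD as a fraction of the neuron's
#'   maximum mean response (default 0.2).
#' @param run_speed_model list: `median` (cm/s, lognormal median of running
#'   trials), `sdlog`, `slow_frac` (fraction of slow trials below 10 cm/s).
#' @param pupil if `TRUE`, Gaussian random-walk pupil covariates are added to
#'   the trial table (for exercising covariate-balanced splitting).
#' @param seed integer RNG seed.
#' @return An object of class `"session_config"`.
#' @export
session_config <- function(n_neurons = 100L, n_elements = 5L,
                           trials_per_condition = 20L,
                           stim_duration_s = 1.0, iti_s = 2.0,
                           frame_rate_hz = 15.45, kernel_tau_s = 1.5,
                           baseline_f0 = 100, neuropil_sd = 1,
                           neuropil_base = 30, neuropil_slow_amp = 3,
                           noise_frac = 0.2,
                           run_speed_model = list(median = 30, sdlog = 0.25,
                                                  slow_frac = 0.1),
                           pupil = FALSE, seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons),
              n_elements = as.integer(n_elements),
              trials_per_condition = as.integer(trials_per_condition),
              stim_duration_s = stim_duration_s, iti_s = iti_s,
              frame_rate_hz = frame_rate_hz, kernel_tau_s = kernel_tau_s,
              baseline_f0 = baseline_f0, neuropil_sd = neuropil_sd,
              neuropil_base = neuropil_base,
              neuropil_slow_amp = neuropil_slow_amp,
              noise_frac = noise_frac,
              run_speed_model = run_speed_model,
              pupil = isTRUE(pupil), seed = as.integer(seed))
  num <- c("stim_duration_s", "iti_s", "frame_rate_hz", "kernel_tau_s",
           "baseline_f0")
  for (f in c("n_neurons", "n_elements", "trials_per_condition", num))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a positive scalar", f))
  structure(cfg, class = "session_config")
}

#' Sample a ground-truth neural population
#'
#' Draws `cfg$n_neurons` ground-truth neurons from a mixture of three kinds:
#' \describe{
#'   \item{labeled_line}{one positive weight, baseline drive near 0 -- a
#'     classical single-element neuron.}
#'   \item{combination}{2--3 positive weights with a strongly negative
#'     baseline drive (threshold), so only the specific multi-element
#'     combination crosses threshold -- supra-linear by construction.}
#'   \item{tabulated}{an arbitrary tabulated tuning vector (no LN form),
#'     useful for misspecification checks.}
#' }
#' Each neuron carries its own trial-noise SD (`noise_frac` x its maximum
#' mean response) and a true neuropil contamination coefficient.
#'
#' @param cfg a [session_config()].
#' @param mixture proportions of (labeled_line, combination, tabulated);
#'   must sum to 1.
#' @param seed RNG seed (default `cfg$seed`).
#' @param tabulated_tuning optional function(n_conditions) returning a
#'   tuning vector for tabulated neurons.
#' @return list of ground-truth neurons; each is a list with `kind`,
#'   `params` (`ln_params`, LN kinds), `tuning` (non-catch mean responses),
#'   `catch_mean`, `trial_noise_sd`, `contamination_k_true`.
#' @export
sample_population <- function(cfg,
                              mixture = c(labeled_line = 0.52,
                                          combination = 0.35,
                                          tabulated = 0.13),
                              seed = cfg$seed, tabulated_tuning = NULL) {
  if (length(mixture) != 3 || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-8)
    stop("'mixture' must be 3 nonnegative proportions summing to 1")
  set.seed(seed)
  space <- enumerate_conditions(cfg$n_elements)
  X <- design_matrix(space)
  n <- cfg$n_neurons
  counts <- floor(mixture * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    add <- order(mixture * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  kinds <- sample(rep(c("labeled_line", "combination", "tabulated"), counts))
  lapply(seq_len(n), function(i) {
    kind <- kinds[i]
    if (kind == "labeled_line") {
      w <- numeric(cfg$n_elements)
      w[sample.int(cfg$n_elements, 1)] <- stats::runif(1, 1.0, 2.0)
      p <- ln_params(w = w, h = stats::runif(1, -0.1, 0.1),
                     a = stats::runif(1, 0.5, 1.5))
    } else if (kind == "combination") {
      k <- sample(2:3, 1)
      w <- numeric(cfg$n_elements)
      # deep threshold: dropping any one target element leaves the drive
      # at least ~1.5 units below threshold, so only the full combination
      # (and its supersets) responds
      w[sample.int(cfg$n_elements, k)] <- stats::runif(k, 2.5, 3.5)
      p <- ln_params(w = w, h = -(sum(w) - stats::runif(1, 0.5, 1.0)),
                     a = stats::runif(1, 0.5, 1.5))
    } else {
      p <- NULL
    }
    if (is.null(p)) {
      tun <- if (is.null(tabulated_tuning)) abs(stats::rnorm(nrow(X), 0, 0.3))
             else tabulated_tuning(nrow(X))
      catch_mean <- 0
    } else {
      tun <- ln_predict(p, X)
      catch_mean <- p$a * static_nonlinearity(p$h)
    }
    list(kind = kind, params = p, tuning = as.numeric(tun),
         catch_mean = catch_mean,
         trial_noise_sd = cfg$noise_frac * max(abs(tun)),
         contamination_k_true = stats::runif(1, 0.3, 0.9))
  })
}

#' Simulate the trial structure and true trial amplitudes
#'
#' Presents every condition (catch included) exactly
#' `cfg$trials_per_condition` times in a seeded pseudo-random order. The true
#' response amplitude of neuron i on a trial of condition s is its mean
#' tuning value (its spontaneous mean for catch) plus Gaussian noise with the
#' neuron's `trial_noise_sd`. Running speeds follow the configured lognormal
#' model with a fraction of slow (<10 cm/s) trials.
#'
#' @param pop population from [sample_population()].
#' @param cfg a [session_config()].
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return list with `trial_table` (data.frame: `condition` index into the
#'   space, `bits`, `is_catch`, `onset_frame`, `offset_frame`,
#'   `iti_end_frame`, `run_speed`, optional pupil columns) and `amplitudes`
#'   (neuron x trial matrix of true response amplitudes).
#' @export
simulate_trials <- function(pop, cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  space <- enumerate_conditions(cfg$n_elements)
  n_cond <- length(space$masks)
  cond_seq <- sample(rep(seq_len(n_cond), cfg$trials_per_condition))
  n_trials <- length(cond_seq)
  stim_frames <- max(1L, round_half_up(cfg$stim_duration_s * cfg$frame_rate_hz))
  iti_frames <- max(1L, round_half_up(cfg$iti_s * cfg$frame_rate_hz))
  trial_len <- stim_frames + iti_frames
  onset <- iti_frames + (seq_len(n_trials) - 1L) * trial_len + 1L
  rsm <- cfg$run_speed_model
  slow <- stats::runif(n_trials) < rsm$slow_frac
  speed <- stats::rlnorm(n_trials, log(rsm$median), rsm$sdlog)
  speed[slow] <- stats::runif(sum(slow), 0, 10)
  tt <- data.frame(condition = cond_seq,
                   bits = space$bits[cond_seq],
                   is_catch = space$is_catch[cond_seq],
                   onset_frame = onset,
                   offset_frame = onset + stim_frames - 1L,
                   iti_end_frame = onset + trial_len - 1L,
                   run_speed = speed,
                   stringsAsFactors = FALSE)
  if (isTRUE(cfg$pupil)) {
    tt$pupil_diameter <- 1 + cumsum(stats::rnorm(n_trials, 0, 0.02))
    tt$pupil_x <- cumsum(stats::rnorm(n_trials, 0, 0.02))
    tt$pupil_y <- cumsum(stats::rnorm(n_trials, 0, 0.02))
  }
  non_catch_id <- cumsum(!space$is_catch)  # condition index -> tuning index
  amp <- t(vapply(pop, function(nr) {
    mu <- ifelse(space$is_catch[cond_seq], nr$catch_mean,
                 nr$tuning[non_catch_id[cond_seq]])
    mu + stats::rnorm(n_trials, 0, nr$trial_noise_sd)
  }, numeric(n_trials)))
  list(trial_table = tt, amplitudes = amp)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Render raw fluorescence traces from trial amplitudes
#'
#' Forward model inverted by the preprocessing stage: each trial amplitude is
#' shaped as a boxcar over the stimulus window, convolved with a unit-area
#' exponential calcium kernel (decay `cfg$kernel_tau_s`), and summed into a
#' dF/F trace. True somatic fluorescence is
#' `baseline_f0 * (1 + dFF)`; the neuropil channel is a shared slow
#' background plus white noise; the recorded ROI channel is the somatic
#' fluorescence plus `contamination_k_true` times the neuropil channel.
#' Rendered fluorescence is clipped at 0.
#'
#' @param amplitudes neuron x trial matrix of true amplitudes.
#' @param trial_table trial table from [simulate_trials()].
#' @param cfg a [session_config()].
#' @param pop population (for per-neuron contamination coefficients).
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return An object of class `"raw_traces"`: list with `R`, `N`
#'   (neuron x time), `frame_rate_hz`.
#' @export
render_traces <- function(amplitudes, trial_table, cfg, pop,
                          seed = cfg$seed + 2L) {
  stopifnot(all(is.finite(amplitudes)))
  set.seed(seed)
  n_neurons <- nrow(amplitudes)
  n_frames <- max(trial_table$iti_end_frame) + 1L
  g <- kernel_decay(cfg)
  stim_frames <- trial_table$offset_frame[1] - trial_table$onset_frame[1] + 1L
  # unit-area kernel: impulse response (1-g) * g^t; recursive filter form
  dff <- matrix(0, n_neurons, n_frames)
  drive <- matrix(0, n_neurons, n_frames)
  for (tr in seq_len(nrow(trial_table))) {
    fr <- trial_table$onset_frame[tr]:trial_table$offset_frame[tr]
    drive[, fr] <- drive[, fr] + amplitudes[, tr]
  }
  for (i in seq_len(n_neurons))
    dff[i, ] <- (1 - g) * stats::filter(drive[i, ], g, method = "recursive")
  f_true <- pmax(cfg$baseline_f0 * (1 + dff), 0)
  phase <- stats::runif(1, 0, 2 * pi)
  slow <- cfg$neuropil_base +
    cfg$neuropil_slow_amp * sin(2 * pi * seq_len(n_frames) /
                                  (60 * cfg$frame_rate_hz) + phase)
  N <- matrix(rep(slow, each = n_neurons), n_neurons, n_frames) +
    matrix(stats::rnorm(n_neurons * n_frames, 0, cfg$neuropil_sd),
           n_neurons, n_frames)
  N <- pmax(N, 0)
  k_true <- vapply(pop, `[[`, numeric(1), "contamination_k_true")
  R <- pmax(f_true + k_true * N, 0)
  structure(list(R = R, N = N, frame_rate_hz = cfg$frame_rate_hz),
            class = "raw_traces")
}

kernel_decay <- function(cfg) exp(-1 / (cfg$frame_rate_hz * cfg$kernel_tau_s))

#' Analytic stimulus-window attenuation of the calcium kernel
#'
#' A sustained boxcar of amplitude A convolved with the unit-area exponential
#' kernel reaches `A (1 - g^(t+1))` at frame t of the window
#' (`g = exp(-1 / (rate * tau))`); the mean dF/F over a W-frame stimulus
#' window is therefore attenuated by
#' `1 - g (1 - g^W) / (W (1 - g))` relative to A.
#'
#' @param cfg a [session_config()].
#' @return scalar attenuation factor in (0, 1).
#' @export
window_attenuation <- function(cfg) {
  g <- kernel_decay(cfg)
  W <- max(1L, round_half_up(cfg$stim_duration_s * cfg$frame_rate_hz))
  1 - g * (1 - g^W) / (W * (1 - g))
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper: [sample_population()], [simulate_trials()],
#' [render_traces()].
#'
#' @param cfg a [session_config()].
#' @param mixture passed to [sample_population()].
#' @param render if `FALSE`, skip trace rendering (trial amplitudes only).
#' @return An object of class `"synthetic_session"`: list with `config`,
#'   `space`, `truth`, `trial_table`, `amplitudes`, `raw` (or `NULL`).
#' @export
simulate_session <- function(cfg = session_config(),
                             mixture = c(labeled_line = 0.52,
                                         combination = 0.35,
                                         tabulated = 0.13),
                             render = TRUE) {
  pop <- sample_population(cfg, mixture = mixture)
  sim <- simulate_trials(pop, cfg)
  raw <- if (isTRUE(render))
    render_traces(sim$amplitudes, sim$trial_table, cfg, pop) else NULL
  structure(list(config = cfg, space = enumerate_conditions(cfg$n_elements),
                 truth = pop, trial_table = sim$trial_table,
                 amplitudes = sim$amplitudes, raw = raw),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(paste0("Synthetic session: %d neurons, %d trials (%d conditions",
                     " x %d), %s traces\n"),
              x$config$n_neurons, nrow(x$trial_table),
              length(x$space$masks), x$config$trials_per_condition,
              if (is.null(x$raw)) "no" else
                sprintf("%d-frame", ncol(x$raw$R))))
  invisible(x)
}
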