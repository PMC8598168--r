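test_that("population mixture is respected and seeded deterministically", {
  cfg <- session_config(n_neurons = 12, seed = 7)
  pop <- sample_population(cfg, mixture = c(1, 0, 0))
  expect_true(all(vapply(pop, `[[`, character(1), "kind") == "labeled_line"))
  for (nr in pop)
    expect_equal(sum(nr$params$w != 0), 1)
  pop2 <- sample_population(cfg, mixture = c(1, 0, 0))
  expect_identical(pop, pop2)
  expect_error(sample_population(cfg, mixture = c(0.5, 0.2, 0.2)),
               "sum")
})

test_that("combination-selective LN neurons are supra-linear by construction", {
  sp <- enumerate_conditions(5)
  X <- design_matrix(sp)
  pred <- ln_predict(ln_params(w = c(1, 1, 0, 0, 0), h = -1.5, a = 1), X)
  pair <- pred[condition_index(sp, c(0, 1))]
  singles <- pred[c(condition_index(sp, 0), condition_index(sp, 1))]
  expect_gt(pair, sum(singles))
  # sampled combination neurons prefer their target combination
  cfg <- session_config(n_neurons = 20, seed = 11)
  pop <- sample_population(cfg, mixture = c(0, 1, 0))
  for (nr in pop) {
    target <- which(nr$params$w > 0) - 1L
    pos <- which(which(!sp$is_catch) == condition_index(sp, target))
    expect_equal(which.max(nr$tuning), pos)
  }
})

test_that("trial simulation has exact condition counts and seeded order", {
  cfg <- session_config(n_neurons = 3, seed = 2)
  pop <- sample_population(cfg)
  sim <- simulate_trials(pop, cfg)
  expect_equal(nrow(sim$trial_table), 32 * 20)
  expect_equal(as.integer(table(sim$trial_table$condition)), rep(20L, 32))
  expect_true(all(diff(sim$trial_table$onset_frame) > 0))
  expect_true(all(sim$trial_table$offset_frame <
                    sim$trial_table$iti_end_frame))
  # counts invariant under seed change
  sim2 <- simulate_trials(pop, cfg, seed = 99)
  expect_equal(table(sim2$trial_table$condition),
               table(sim$trial_table$condition))
  # zero noise: amplitudes equal the tuning values exactly
  cfg0 <- session_config(n_neurons = 3, noise_frac = 0, seed = 2)
  pop0 <- sample_population(cfg0)
  sim0 <- simulate_trials(pop0, cfg0)
  sp <- enumerate_conditions(5)
  non_catch_id <- cumsum(!sp$is_catch)
  for (i in 1:3) {
    expected <- ifelse(sp$is_catch[sim0$trial_table$condition],
                       pop0[[i]]$catch_mean,
                       pop0[[i]]$tuning[non_catch_id[sim0$trial_table$condition]])
    expect_equal(sim0$amplitudes[i, ], expected)
  }
})

test_that("rendered traces follow the forward model", {
  # zero amplitudes, no neuropil noise or drift: R is constant
  cfg <- session_config(n_neurons = 2, trials_per_condition = 1,
                        neuropil_sd = 0, neuropil_slow_amp = 0,
                        noise_frac = 0, seed = 3)
  pop <- sample_population(cfg, mixture = c(1, 0, 0))
  sim <- simulate_trials(pop, cfg)
  amp0 <- sim$amplitudes * 0
  raw <- render_traces(amp0, sim$trial_table, cfg, pop)
  for (i in 1:2) {
    expect_equal(stats::sd(raw$R[i, ]), 0)
    expect_equal(raw$R[i, 1],
                 cfg$baseline_f0 +
                   pop[[i]]$contamination_k_true * cfg$neuropil_base)
  }
  expect_identical(render_traces(amp0, sim$trial_table, cfg, pop),
                   render_traces(amp0, sim$trial_table, cfg, pop))
})

test_that("the pipeline recovers trial amplitudes up to the analytic kernel attenuation", {
  # long ITIs so transients die out; true k = 1 makes min-ratio correction exact
  cfg <- session_config(n_neurons = 4, trials_per_condition = 1,
                        iti_s = 10, kernel_tau_s = 0.5,
                        neuropil_sd = 0, neuropil_slow_amp = 0,
                        noise_frac = 0, seed = 5)
  pop <- sample_population(cfg, mixture = c(0.5, 0.5, 0))
  for (i in seq_along(pop)) pop[[i]]$contamination_k_true <- 1
  sim <- simulate_trials(pop, cfg)
  raw <- render_traces(sim$amplitudes, sim$trial_table, cfg, pop)
  corr <- neuropil_correct(raw)
  expect_equal(corr$k, rep(1, 4), tolerance = 1e-12)
  dff <- dff_catch_baseline(corr, sim$trial_table)
  expect_equal(dff$f0, rep(cfg$baseline_f0, 4), tolerance = 1e-7)
  resp <- trial_responses(dff, sim$trial_table, enumerate_conditions(5))
  att <- window_attenuation(cfg)
  expect_equal(resp$values, sim$amplitudes * att, tolerance = 1e-6)
})

test_that("end-to-end tuning estimates track ground truth at low noise", {
  cfg <- session_config(n_neurons = 8, noise_frac = 0.05, seed = 6)
  ses <- simulate_session(cfg)
  corr <- neuropil_correct(ses$raw)
  dff <- dff_catch_baseline(corr, ses$trial_table)
  resp <- filter_responses(trial_responses(dff, ses$trial_table, ses$space))
  att <- window_attenuation(cfg)
  for (i in seq_len(cfg$n_neurons)) {
    tc <- tuning_curve(resp, i, n_boot = 0)
    truth <- ses$truth[[i]]$tuning - ses$truth[[i]]$catch_mean
    expect_gt(stats::cor(tc$values, truth * att), 0.95)
  }
})

test_that("session round trip through disk is lossless", {
  cfg <- session_config(n_neurons = 3, trials_per_condition = 2, seed = 8,
                        pupil = TRUE)
  ses <- simulate_session(cfg)
  path <- file.path(tempdir(), "ses-roundtrip")
  on.exit(unlink(path, recursive = TRUE))
  write_session(ses, path)
  back <- read_session(path)
  expect_identical(back$trial_table$condition, ses$trial_table$condition)
  expect_identical(back$trial_table$onset_frame, ses$trial_table$onset_frame)
  expect_equal(back$amplitudes, ses$amplitudes, tolerance = 1e-12)
  expect_equal(back$raw$R, ses$raw$R, tolerance = 1e-12)
  expect_equal(back$truth[[1]]$tuning, ses$truth[[1]]$tuning,
               tolerance = 1e-12)
  expect_equal(back$truth[[2]]$params$w, ses$truth[[2]]$params$w,
               tolerance = 1e-12)
  # truncated session names the missing file
  file.remove(file.path(path, "amplitudes.tsv"))
  expect_error(read_session(path), "amplitudes.tsv")
  # schema version mismatch is an explicit error
  manifest <- jsonlite::read_json(file.path(path, "session.json"))
  manifest$schema_version <- 99
  jsonlite::write_json(manifest, file.path(path, "session.json"),
                       auto_unbox = TRUE)
  expect_error(read_session(path), "schema version")
})
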