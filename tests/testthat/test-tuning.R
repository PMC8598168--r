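make_flat_resp <- function(value = 2, n_per = 6) {
  sp <- enumerate_conditions(5)
  tt <- data.frame(condition = rep(seq_len(32), each = n_per),
                   is_catch = rep(sp$is_catch, each = n_per),
                   run_speed = 20)
  response_matrix(matrix(value, 1, nrow(tt)), tt, sp)
}

test_that("tuning curves are catch-subtracted means of inlier trials", {
  resp <- make_flat_resp(2)
  tc <- tuning_curve(resp, 1, n_boot = 0)
  expect_true(all(tc$values == 0))
  expect_equal(tc$catch_mean, 2)
  expect_equal(unname(tc$n_trials), rep(6L, 31))
})

test_that("noiseless LN tuning is recovered exactly through the trial layer", {
  cfg <- session_config(n_neurons = 4, noise_frac = 0, seed = 31)
  pop <- sample_population(cfg, mixture = c(0.5, 0.5, 0))
  sim <- simulate_trials(pop, cfg)
  sp <- enumerate_conditions(5)
  resp <- response_matrix(sim$amplitudes, sim$trial_table, sp)
  for (i in 1:4) {
    tc <- tuning_curve(resp, i, n_boot = 0)
    expect_equal(tc$values, pop[[i]]$tuning - pop[[i]]$catch_mean,
                 tolerance = 1e-9)
  }
})

test_that("preferred stimulus is the argmax with the documented tie rules", {
  resp <- make_flat_resp(0)
  sp <- resp$space
  tc <- tuning_curve(resp, 1, n_boot = 0)
  target <- condition_index(sp, c(0, 2, 3))   # C2+B1+D1
  tc$values[match(target, which(!sp$is_catch))] <- 1
  expect_equal(preferred_stimulus(tc), target)
  # all equal: first singleton in canonical order
  tc$values[] <- 0.5
  expect_equal(preferred_stimulus(tc), condition_index(sp, 0))
  # single finite value wins
  tc$values[] <- NA_real_
  tc$values[10] <- 0.1
  expect_equal(preferred_stimulus(tc), which(!sp$is_catch)[10])
})

test_that("principal whisker is the largest per-element OLS coefficient", {
  sp <- enumerate_conditions(5)
  X <- design_matrix(sp)
  n_per <- 2
  tt <- data.frame(condition = rep(seq_len(32), each = n_per),
                   is_catch = rep(sp$is_catch, each = n_per),
                   run_speed = 20)
  pres <- rbind(X, 0)[tt$condition, ]   # per-trial element presence
  # responds 1 iff element 3 present
  v1 <- matrix(pres[, 4], 1)
  resp1 <- response_matrix(v1, tt, sp)
  pw1 <- principal_whisker(resp1, 1)
  expect_equal(as.integer(pw1), 3L)
  expect_equal(unname(attr(pw1, "coefficients")), c(0, 0, 0, 1, 0),
               tolerance = 1e-10)
  # additive neuron 0.2 x1 + 0.7 x4 (1-based elements 1 and 4)
  v2 <- matrix(0.2 * pres[, 1] + 0.7 * pres[, 4], 1)
  pw2 <- principal_whisker(response_matrix(v2, tt, sp), 1)
  expect_equal(as.integer(pw2), 3L)   # 0-based index of element 4
  # exact tie: lower element index wins
  v3 <- matrix(pres[, 2] + pres[, 5], 1)
  expect_equal(as.integer(principal_whisker(response_matrix(v3, tt, sp), 1)),
               1L)
})

test_that("linear difference measures deviation from component sums", {
  resp <- make_flat_resp(0)
  sp <- resp$space
  conds <- which(!sp$is_catch)
  tc <- tuning_curve(resp, 1, n_boot = 0)
  tc$values[] <- 0
  tc$values[match(condition_index(sp, 1), conds)] <- 0.3
  tc$values[match(condition_index(sp, 2), conds)] <- 0.2
  tc$values[match(condition_index(sp, c(1, 2)), conds)] <- 1.0
  ld <- linear_difference(tc)
  expect_equal(unname(ld$ld[ld$conditions == condition_index(sp, c(1, 2))]),
               0.5)
  # perfectly linear tuning: ld identically 0
  X <- design_matrix(sp)
  tc$values <- as.numeric(X %*% c(0.1, 0.4, 0.2, 0, 0.3))
  expect_true(all(abs(linear_difference(tc)$ld) < 1e-9))
  # linearity: ld(t1 + t2) = ld(t1) + ld(t2)
  t1 <- tc; t1$values <- stats::rnorm(31)
  t2 <- tc; t2$values <- stats::rnorm(31)
  tsum <- tc; tsum$values <- t1$values + t2$values
  expect_equal(linear_difference(tsum)$ld,
               linear_difference(t1)$ld + linear_difference(t2)$ld)
})

test_that("threshold-LN neurons have positive ld at their preferred stimulus", {
  sp <- enumerate_conditions(5)
  cfg <- session_config(n_neurons = 10, noise_frac = 0, seed = 33)
  pop <- sample_population(cfg, mixture = c(0, 1, 0))
  sim <- simulate_trials(pop, cfg)
  resp <- response_matrix(sim$amplitudes, sim$trial_table, sp)
  for (i in 1:10) {
    tc <- tuning_curve(resp, i, n_boot = 0)
    ld <- linear_difference(tc)
    pref <- preferred_stimulus(tc)
    ld_pref <- ld$ld[ld$conditions == pref]
    expect_gt(ld_pref, 0)
    # an LN neuron with nonnegative weights and the convex f is never
    # sub-linear; below-threshold combinations sit near ld = 0, so most
    # non-preferred multis carry only a small fraction of the peak ld
    others <- ld$ld[ld$conditions != pref]
    expect_gte(mean(others < 0.2 * ld_pref), 0.5)
    expect_true(all(ld$ld > -1e-9))
  }
})

test_that("bootstrap CIs bracket the tuning values", {
  ses <- amp_session(n_neurons = 2, seed = 35)
  resp <- ses$resp
  tc <- tuning_curve(resp, 1, n_boot = 300, seed = 1)
  ok <- is.finite(tc$values)
  expect_true(all(tc$ci_low[ok] <= tc$values[ok] + 1e-9))
  expect_true(all(tc$ci_high[ok] >= tc$values[ok] - 1e-9))
  # seeded bootstrap is reproducible
  tc2 <- tuning_curve(resp, 1, n_boot = 300, seed = 1)
  expect_identical(tc$ci_low, tc2$ci_low)
})

test_that("trial partitions are balanced per condition and covariates", {
  ses <- amp_session(n_neurons = 1, seed = 41, pupil = TRUE)
  tt <- ses$trial_table
  halves <- partition_trials(tt, 2, seed = 1)
  counts <- table(tt$condition, halves)
  expect_true(all(counts == 10))
  thirds <- partition_trials(tt, 3, seed = 1)
  counts3 <- table(tt$condition, thirds)
  expect_true(all(abs(counts3 - 20 / 3) < 1))
  expect_true(all(rowSums(counts3) == 20))
  # covariate-balanced split beats the median random split
  bal_diff <- function(lab, col)
    abs(diff(tapply(tt[[col]], lab, mean)))
  bal <- partition_trials(tt, 2, balance_cols = "pupil_diameter", seed = 2)
  set.seed(3)
  rand_diffs <- replicate(40, bal_diff(partition_trials(tt, 2), "pupil_diameter"))
  expect_lte(bal_diff(bal, "pupil_diameter"), stats::median(rand_diffs))
  expect_error(partition_trials(tt[1:5, ], 3), "fewer than")
})

test_that("reliability is the Pearson correlation between partition curves", {
  resp <- make_flat_resp(0)
  ta <- tuning_curve(resp, 1, n_boot = 0)
  ta$values <- stats::rnorm(31)
  tb <- ta
  expect_equal(reliability(ta, tb), 1)
  tb$values <- -ta$values
  expect_equal(reliability(ta, tb), -1)
  tb$values <- rep(1, 31)
  expect_true(is.na(reliability(ta, tb)))
  expect_match(attr(reliability(ta, tb), "reason"), "variance")
  # independent noise curves: mean correlation near 0
  set.seed(5)
  rs <- replicate(500, {
    ta$values <- stats::rnorm(31); tb$values <- stats::rnorm(31)
    reliability(ta, tb)
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("a comprehensive noiseless population yields a block-diagonal matrix", {
  sp <- enumerate_conditions(5)
  conds <- which(!sp$is_catch)
  n_per <- 4
  tt <- data.frame(condition = rep(seq_len(32), each = n_per),
                   is_catch = rep(sp$is_catch, each = n_per),
                   run_speed = 20)
  # one dedicated neuron per condition, tiny deterministic jitter for
  # nonzero reliability variance
  set.seed(6)
  v <- t(vapply(seq_along(conds), function(i) {
    mu <- ifelse(tt$condition == conds[i], 1, 0)
    mu + stats::rnorm(nrow(tt), 0, 1e-3)
  }, numeric(nrow(tt))))
  resp <- response_matrix(v, tt, sp)
  pm <- population_matrices(resp, "halves", seed = 1)
  expect_equal(nrow(pm$tuning$matrix), 31)
  expect_equal(pm$tuning$preferred, conds)   # rows cover all 31 conditions
  for (i in seq_len(31))
    expect_equal(which.max(pm$tuning$matrix[i, ]), i,
                 ignore_attr = TRUE)
  # impossible reliability threshold empties the matrix
  expect_warning(pm_inf <- population_matrices(resp, "halves",
                                               r_thresh = Inf, seed = 1),
                 "no neuron")
  expect_equal(nrow(pm_inf$tuning$matrix), 0)
})

test_that("sorted linear difference averages held-out ld by train rank", {
  sp <- enumerate_conditions(5)
  conds <- which(!sp$is_catch)
  multis <- multi_conditions(sp)
  # single neuron: curve equals that neuron's own sorted ld
  train <- matrix(stats::rnorm(31), 1)
  train[1, match(multis[7], conds)] <- 10   # multi-preferring
  ld <- matrix(stats::rnorm(26), 1)
  sl <- sorted_linear_difference(train, ld, sp)
  expect_equal(sl$n_neurons, 1L)
  rk <- order(train[1, match(multis, conds)], decreasing = TRUE)
  expect_equal(sl$mean_ld, ld[1, rk])
  # singleton-preferring neurons are excluded
  train2 <- train; train2[1, match(multis[7], conds)] <- -10
  train2[1, 1] <- 99
  expect_equal(sorted_linear_difference(train2, ld, sp)$n_neurons, 0L)
  # linear population: all ranks near zero
  set.seed(7)
  X <- design_matrix(sp)
  n <- 40
  tr <- te <- matrix(NA_real_, n, 31)
  ldm <- matrix(NA_real_, n, 26)
  for (i in seq_len(n)) {
    w <- stats::runif(5, 0.5, 1)
    tr[i, ] <- as.numeric(X %*% w) + stats::rnorm(31, 0, 0.05)
    telin <- as.numeric(X %*% w) + stats::rnorm(31, 0, 0.05)
    tc <- tuning_curve(make_flat_resp(0), 1, n_boot = 0)
    tc$values <- telin
    ldm[i, ] <- linear_difference(tc)$ld
  }
  sl2 <- sorted_linear_difference(tr, ldm, sp)
  expect_true(all(abs(sl2$mean_ld) < 0.2))
})

test_that("deterministic supra-linear responses give p_supra = 0", {
  sp <- enumerate_conditions(5)
  cfg <- session_config(n_neurons = 1, noise_frac = 0, seed = 51)
  pop <- sample_population(cfg, mixture = c(0, 1, 0))
  sim <- simulate_trials(pop, cfg)
  resp <- response_matrix(sim$amplitudes, sim$trial_table, sp)
  parts <- partition_trials(sim$trial_table, 2, seed = 1)
  st <- supralinearity_test(resp, 1, which(parts == 1), which(parts == 2),
                            n_boot = 500, seed = 2)
  expect_equal(st$label, "supra")
  expect_equal(st$p_supra, 0)
  expect_gt(st$ld_top, 0)
})

test_that("supra-linearity test declines when the top stimulus is a singleton", {
  # zero noise: ties resolve to the singleton by the subset-size rule
  ses <- amp_session(n_neurons = 4, mixture = c(1, 0, 0), noise_frac = 0,
                     seed = 53)
  parts <- partition_trials(ses$trial_table, 2, seed = 1)
  st <- supralinearity_test(ses$resp, 1, which(parts == 1),
                            which(parts == 2), n_boot = 200, seed = 2)
  expect_equal(st$label, "ns")
  expect_match(st$reason, "not multi-element")
})
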