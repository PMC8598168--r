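condition_values <- function(resp, neuron, trials = NULL) {
  use <- resp$state & resp$inlier[neuron, ]
  if (!is.null(trials)) {
    keep <- logical(length(use))
    keep[trials] <- TRUE
    use <- use & keep
  }
  tt <- resp$trial_table
  lapply(seq_along(resp$space$masks), function(c_id)
    resp$values[neuron, tt$condition == c_id & use])
}

boot_means <- function(v, n_boot) {
  m <- length(v)
  if (m == 0) return(rep(NA_real_, n_boot))
  if (m == 1) return(rep(v, n_boot))
  .colMeans(v[sample.int(m, m * n_boot, replace = TRUE)], m, n_boot)
}

#' Catch-subtracted tuning curve with bootstrap confidence intervals
#'
#' The tuning value for each non-catch condition is the mean inlier in-state
#' response minus the mean catch response. 95% confidence intervals are
#' percentile bootstrap over trial resampling within condition, with the
#' catch mean re-drawn in every replicate.
#'
#' @param resp a `response_matrix`.
#' @param neuron neuron index.
#' @param n_boot bootstrap replicates (default 1000; 0 skips the bootstrap).
#' @param seed optional RNG seed.
#' @param trials optional trial indices restricting the computation (e.g. a
#'   cross-validation partition).
#' @param conf confidence level (default 0.95).
#' @return An object of class `"tuning_curve"`: `values`, `ci_low`,
#'   `ci_high`, `n_trials` (per non-catch condition, canonical order),
#'   `catch_mean`, `boot` (replicate curves, conditions x `n_boot`),
#'   `space`.
#' @export
tuning_curve <- function(resp, neuron, n_boot = 1000, seed = NULL,
                         trials = NULL, conf = 0.95) {
  stopifnot(inherits(resp, "response_matrix"))
  if (!is.null(seed)) set.seed(seed)
  space <- resp$space
  catch_id <- which(space$is_catch)
  if (length(catch_id) != 1) stop("tuning requires catch trials")
  vals <- condition_values(resp, neuron, trials)
  catch_v <- vals[[catch_id]]
  if (length(catch_v) == 0) stop("no usable catch trials for this neuron")
  conds <- which(!space$is_catch)
  n_trials <- lengths(vals)[conds]
  means <- vapply(vals[conds], function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))
  values <- means - mean(catch_v)
  ci_low <- ci_high <- rep(NA_real_, length(conds))
  boot <- NULL
  if (n_boot > 0) {
    catch_b <- boot_means(catch_v, n_boot)
    boot <- matrix(NA_real_, length(conds), n_boot)
    for (j in seq_along(conds))
      if (n_trials[j] > 0)
        boot[j, ] <- boot_means(vals[[conds[j]]], n_boot) - catch_b
    a <- (1 - conf) / 2
    qs <- apply(boot, 1, function(r)
      if (all(is.na(r))) c(NA_real_, NA_real_)
      else stats::quantile(r, c(a, 1 - a), na.rm = TRUE, names = FALSE))
    ci_low <- qs[1, ]; ci_high <- qs[2, ]
  }
  structure(list(values = values, ci_low = ci_low, ci_high = ci_high,
                 n_trials = n_trials, catch_mean = mean(catch_v),
                 boot = boot, space = space),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("Tuning curve over %d conditions; peak %.4g at %s\n",
              length(x$values), max(x$values, na.rm = TRUE),
              condition_labels(x$space)[preferred_stimulus(x)]))
  invisible(x)
}

#' Preferred stimulus of a tuning curve
#'
#' The condition with the largest tuning value; exact ties are broken toward
#' the smaller subset size, then canonical order (i.e. the first maximal
#' condition in canonical order).
#'
#' @param t a `tuning_curve`.
#' @return condition index into the stimulus space.
#' @export
preferred_stimulus <- function(t) {
  stopifnot(inherits(t, "tuning_curve"))
  conds <- which(!t$space$is_catch)
  ok <- is.finite(t$values)
  if (!any(ok)) stop("tuning curve has no finite values")
  best <- which(t$values == max(t$values[ok]) & ok)[1]
  conds[best]
}

#' Principal element from a per-trial linear fit
#'
#' Ordinary least squares of single-trial responses on per-element presence
#' indicators plus an intercept; the principal element (principal whisker)
#' is the element with the largest coefficient, ties broken toward the lower
#' element index.
#'
#' @param resp a `response_matrix`.
#' @param neuron neuron index.
#' @return 0-based element index, with the fitted coefficients as attribute
#'   `"coefficients"`.
#' @export
principal_whisker <- function(resp, neuron) {
  space <- resp$space
  use <- which(resp$state & resp$inlier[neuron, ])
  if (length(use) == 0) stop("no usable trials")
  X <- t(vapply(resp$trial_table$condition[use], function(c_id) {
    row <- numeric(space$n_elements)
    row[space$masks[[c_id]] + 1L] <- 1
    row
  }, numeric(space$n_elements)))
  pres <- colSums(X)
  bad <- which(pres == 0 | pres == nrow(X))
  if (length(bad))
    stop(sprintf("element '%s' is never/always present among usable trials",
                 space$element_labels[bad[1]]))
  fit <- stats::lm.fit(cbind(1, X), resp$values[neuron, use])
  beta <- fit$coefficients[-1]
  pw <- which(beta == max(beta))[1] - 1L
  structure(pw, coefficients = stats::setNames(beta, space$element_labels))
}

#' Linear-difference statistic
#'
#' For every multi-element condition s, the linear difference is the
#' observed (catch-subtracted) tuning value minus the linear sum of its
#' single-element component values:
#' `ld(s) = value(s) - sum_{j in s} value({j})`. Positive values indicate
#' supra-linear, negative values sub-linear spatial summation. Bootstrap
#' confidence intervals are derived from the tuning curve's replicate curves
#' when present.
#'
#' @param t a `tuning_curve` (all singleton values must be finite; multi
#'   conditions with a missing singleton are flagged `NA`).
#' @return An object of class `"linear_difference"`: `ld`, `ci_low`,
#'   `ci_high` (named by condition bit-string, canonical multi order),
#'   `conditions` (condition indices), `space`.
#' @export
linear_difference <- function(t) {
  stopifnot(inherits(t, "tuning_curve"))
  space <- t$space
  conds <- which(!space$is_catch)
  pos <- function(c_id) match(c_id, conds)
  multis <- multi_conditions(space)
  comp <- lapply(multis, function(m) pos(singleton_components(space, m)))
  ld <- vapply(seq_along(multis), function(j) {
    s <- pos(multis[j])
    t$values[s] - sum(t$values[comp[[j]]])
  }, numeric(1))
  ci_low <- ci_high <- rep(NA_real_, length(multis))
  if (!is.null(t$boot)) {
    for (j in seq_along(multis)) {
      reps <- t$boot[pos(multis[j]), ] -
        colSums(t$boot[comp[[j]], , drop = FALSE])
      if (!all(is.na(reps))) {
        q <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                             names = FALSE)
        ci_low[j] <- q[1]; ci_high[j] <- q[2]
      }
    }
  }
  names(ld) <- space$bits[multis]
  structure(list(ld = ld, ci_low = ci_low, ci_high = ci_high,
                 conditions = multis, space = space),
            class = "linear_difference")
}

#' Partition trials for cross-validation
#'
#' Assigns trials to `n_parts` partitions with per-condition counts
#' differing by at most one. When covariate columns (e.g. pupil diameter
#' and location) are named, a greedy within-condition swap refinement
#' minimizes the between-partition difference in covariate means.
#'
#' @param trial_table trial table.
#' @param n_parts 2 (halves) or 3 (thirds).
#' @param balance_cols optional character vector of covariate column names.
#' @param seed RNG seed.
#' @param n_swaps refinement iterations (default 400).
#' @return integer partition labels (1..n_parts), one per trial.
#' @export
partition_trials <- function(trial_table, n_parts = 2, balance_cols = NULL,
                             seed = NULL, n_swaps = 400) {
  stopifnot(n_parts %in% c(2, 3))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trial_table)
  labels <- integer(n)
  for (c_id in unique(trial_table$condition)) {
    idx <- which(trial_table$condition == c_id)
    if (length(idx) < n_parts)
      stop(sprintf("condition %s has fewer than %d trials", c_id, n_parts))
    labels[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_parts),
                                                    length(idx))
  }
  if (!is.null(balance_cols) && length(balance_cols)) {
    covs <- as.matrix(trial_table[, balance_cols, drop = FALSE])
    sds <- apply(covs, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    objective <- function(lab) {
      tot <- 0
      for (k in seq_len(ncol(covs))) {
        mu <- tapply(covs[, k], lab, mean)
        tot <- tot + sum(abs(outer(mu, mu, "-"))) / (2 * sds[k])
      }
      tot
    }
    cur <- objective(labels)
    for (it in seq_len(n_swaps)) {
      c_id <- sample(unique(trial_table$condition), 1)
      idx <- which(trial_table$condition == c_id)
      pq <- sample.int(n_parts, 2)
      a <- idx[labels[idx] == pq[1]]; b <- idx[labels[idx] == pq[2]]
      if (!length(a) || !length(b)) next
      i <- sample(a, 1); j <- sample(b, 1)
      lab2 <- labels
      lab2[c(i, j)] <- lab2[c(j, i)]
      new <- objective(lab2)
      if (new < cur) { labels <- lab2; cur <- new }
    }
  }
  labels
}

#' Split-partition tuning reliability
#'
#' Pearson correlation between two tuning curves computed on disjoint trial
#' partitions, over conditions finite in both. Used to gate neurons at
#' `r > 0.5`.
#'
#' @param t_a,t_b `tuning_curve`s.
#' @return scalar correlation, or `NA` with a `"reason"` attribute (fewer
#'   than 3 shared conditions, or zero variance in either curve).
#' @export
reliability <- function(t_a, t_b) {
  ok <- is.finite(t_a$values) & is.finite(t_b$values)
  if (sum(ok) < 3)
    return(structure(NA_real_, reason = "fewer than 3 shared conditions"))
  if (stats::sd(t_a$values[ok]) == 0 || stats::sd(t_b$values[ok]) == 0)
    return(structure(NA_real_, reason = "zero variance in a tuning curve"))
  stats::cor(t_a$values[ok], t_b$values[ok])
}

#' Cross-validated population tuning and linear-difference matrices
#'
#' Splits trials into halves or thirds (balanced per condition and, when
#' pupil covariates are present, for pupil diameter and location). For the
#' halves scheme, neurons pass if the Pearson correlation between tuning
#' curves on the two halves exceeds `r_thresh`; half 1 estimates stimulus
#' preference (row order) and half 2 is displayed. For the thirds scheme,
#' reliability and preference use thirds 1 and 2 only, and third 3 is
#' displayed -- no display data enters selection or sorting. Displayed rows
#' are optionally normalized by their maximum absolute displayed value.
#'
#' @param resp a `response_matrix` (filters applied).
#' @param scheme `"halves"` or `"thirds"`.
#' @param r_thresh reliability gate (default 0.5).
#' @param normalize divide each displayed row by its max absolute value?
#' @param seed RNG seed for the partition.
#' @param parts optional precomputed partition labels (overrides `seed`).
#' @return list with elements `tuning` and `ld`, each of class
#'   `"population_matrix"`: `matrix` (rows = passing neurons in preferred-
#'   stimulus order, columns = the 31 conditions; LD columns are `NA` for
#'   single-element conditions), `neurons`, `preferred` (condition index per
#'   row), `reliability`, `scheme`, `r_thresh`, `seed`, plus the partition
#'   labels as `parts`.
#' @export
population_matrices <- function(resp, scheme = c("halves", "thirds"),
                                r_thresh = 0.5, normalize = TRUE,
                                seed = NULL, parts = NULL) {
  scheme <- match.arg(scheme)
  n_parts <- if (scheme == "halves") 2L else 3L
  tt <- resp$trial_table
  balance_cols <- intersect(c("pupil_diameter", "pupil_x", "pupil_y"),
                            names(tt))
  if (is.null(parts))
    parts <- partition_trials(tt, n_parts,
                              balance_cols = if (length(balance_cols))
                                balance_cols else NULL,
                              seed = seed)
  n <- nrow(resp$values)
  space <- resp$space
  conds <- which(!space$is_catch)
  multis <- multi_conditions(space)
  rel <- rep(NA_real_, n)
  pref <- rep(NA_integer_, n)
  test_vals <- matrix(NA_real_, n, length(conds))
  test_ld <- matrix(NA_real_, n, length(conds))
  for (i in seq_len(n)) {
    curves <- lapply(seq_len(n_parts), function(p)
      tryCatch(tuning_curve(resp, i, n_boot = 0, trials = which(parts == p)),
               error = function(e) NULL))
    if (any(vapply(curves, is.null, logical(1)))) next
    rel[i] <- reliability(curves[[1]], curves[[2]])
    if (!is.finite(rel[i]) || rel[i] <= r_thresh) next
    train <- if (scheme == "halves") curves[[1]]
             else tryCatch(tuning_curve(resp, i, n_boot = 0,
                                        trials = which(parts %in% 1:2)),
                           error = function(e) NULL)
    if (is.null(train)) next
    pref[i] <- preferred_stimulus(train)
    test <- curves[[n_parts]]
    test_vals[i, ] <- test$values
    ldt <- linear_difference(test)
    test_ld[i, match(ldt$conditions, conds)] <- ldt$ld
  }
  pass <- which(!is.na(pref))
  ord <- pass[order(pref[pass], pass)]
  norm_rows <- function(m) {
    if (!normalize) return(m)
    t(apply(m, 1, function(r) {
      mx <- max(abs(r), na.rm = TRUE)
      if (is.finite(mx) && mx > 0) r / mx else r
    }))
  }
  mk <- function(m, kind) {
    mm <- m[ord, , drop = FALSE]
    if (length(ord)) mm <- norm_rows(mm)
    colnames(mm) <- space$bits[conds]
    structure(list(matrix = mm, neurons = ord, preferred = pref[ord],
                   reliability = rel[ord], scheme = scheme,
                   r_thresh = r_thresh, seed = seed, kind = kind,
                   parts = parts, space = space),
              class = "population_matrix")
  }
  if (length(ord) == 0)
    warning("no neuron passes the reliability threshold")
  list(tuning = mk(test_vals, "tuning"), ld = mk(test_ld, "ld"))
}

#' @export
print.population_matrix <- function(x, ...) {
  cat(sprintf("Population %s matrix: %d neurons x %d conditions (%s, r > %g)\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), x$scheme, x$r_thresh))
  invisible(x)
}

#' Rank-sorted linear difference averaged across neurons
#'
#' For every neuron whose train-partition preferred stimulus is
#' multi-element, the multi-element conditions are ranked by descending
#' train-partition tuning value; the held-out-partition linear differences
#' are then averaged at each rank across neurons. Reproduces the population
#' profile in which supra-linearity is confined to the top-ranked stimulus
#' and later ranks are sub-linear.
#'
#' @param train_tuning neurons x conditions matrix of train-partition tuning
#'   values (non-catch, canonical order).
#' @param test_ld neurons x n_multi matrix of held-out linear differences
#'   (canonical multi order).
#' @param space the `stimulus_space`.
#' @return list with `mean_ld` (per rank), `n_neurons`.
#' @export
sorted_linear_difference <- function(train_tuning, test_ld, space) {
  conds <- which(!space$is_catch)
  multis <- multi_conditions(space)
  mpos <- match(multis, conds)
  stopifnot(ncol(train_tuning) == length(conds),
            ncol(test_ld) == length(multis))
  acc <- matrix(NA_real_, nrow(train_tuning), length(multis))
  used <- 0L
  for (i in seq_len(nrow(train_tuning))) {
    tr <- train_tuning[i, ]
    if (!any(is.finite(tr))) next
    best <- which(tr == max(tr, na.rm = TRUE))[1]
    if (!(conds[best] %in% multis)) next   # preferred stimulus must be multi
    used <- used + 1L
    rk <- order(tr[mpos], decreasing = TRUE)
    acc[used, ] <- test_ld[i, rk]
  }
  if (used == 0) return(list(mean_ld = rep(NA_real_, length(multis)),
                             n_neurons = 0L))
  list(mean_ld = colMeans(acc[seq_len(used), , drop = FALSE], na.rm = TRUE),
       n_neurons = used)
}

#' Per-neuron supra-linearity bootstrap test
#'
#' Tests whether a neuron's summation is more supra-linear for its
#' top-ranked stimulus (ranked on a training partition) than for the other
#' multi-element stimuli, on held-out test-partition data. The statistic is
#' `D = ld(top) - mean(ld(other multis))`, a fixed linear functional of the
#' per-condition mean responses; its null distribution is obtained by
#' resampling test-partition trials with replacement within each condition
#' (catch included). `p_supra` is the fraction of replicates with
#' `D <= 0`, `p_sub` the fraction with `D >= 0`; the neuron is labelled
#' `"supra"` (`p_supra < alpha`), `"sub"` (`p_sub < alpha`) or `"ns"`.
#'
#' @param resp a `response_matrix`.
#' @param neuron neuron index.
#' @param train_trials,test_trials disjoint trial-index sets.
#' @param n_boot bootstrap replicates (default 10000).
#' @param alpha per-side level (default 0.01).
#' @param seed optional RNG seed.
#' @return An object of class `"supralinearity_result"`: `ld_top`,
#'   `ld_nontop_mean`, `D`, `p_supra`, `p_sub`, `label`, `top` (condition
#'   index), `reason` (when `label` is `"ns"` for a structural reason).
#' @export
supralinearity_test <- function(resp, neuron, train_trials, test_trials,
                                n_boot = 10000, alpha = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  space <- resp$space
  ns_result <- function(reason)
    structure(list(ld_top = NA_real_, ld_nontop_mean = NA_real_,
                   D = NA_real_, p_supra = NA_real_, p_sub = NA_real_,
                   label = "ns", top = NA_integer_, reason = reason),
              class = "supralinearity_result")
  train <- tryCatch(tuning_curve(resp, neuron, n_boot = 0,
                                 trials = train_trials),
                    error = function(e) NULL)
  if (is.null(train)) return(ns_result("no usable training trials"))
  top <- preferred_stimulus(train)
  multis <- multi_conditions(space)
  if (!(top %in% multis))
    return(ns_result("train-preferred stimulus is not multi-element"))
  others <- setdiff(multis, top)
  catch_id <- which(space$is_catch)

  # D is linear in the 32 per-condition means: build its coefficient vector
  cf <- numeric(length(space$masks))
  add_ld <- function(cf, s, wgt) {
    cf[s] <- cf[s] + wgt
    sc <- singleton_components(space, s)
    cf[sc] <- cf[sc] - wgt
    cf[catch_id] <- cf[catch_id] + wgt * (length(sc) - 1)
    cf
  }
  cf <- add_ld(cf, top, 1)
  for (o in others) cf <- add_ld(cf, o, -1 / length(others))

  vals <- condition_values(resp, neuron, test_trials)
  needed <- which(cf != 0)
  if (any(lengths(vals[needed]) < 2))
    return(ns_result("fewer than 2 test trials in a required condition"))
  m_obs <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  D <- sum(cf[needed] * m_obs[needed])
  M <- matrix(0, length(needed), n_boot)
  for (j in seq_along(needed))
    M[j, ] <- boot_means(vals[[needed[j]]], n_boot)
  Db <- as.numeric(crossprod(cf[needed], M))
  p_supra <- mean(Db <= 0)
  p_sub <- mean(Db >= 0)
  label <- if (p_supra < alpha) "supra" else if (p_sub < alpha) "sub" else "ns"

  test <- tuning_curve(resp, neuron, n_boot = 0, trials = test_trials)
  ldt <- linear_difference(test)
  ld_top <- ldt$ld[match(top, ldt$conditions)]
  ld_nontop <- mean(ldt$ld[match(others, ldt$conditions)], na.rm = TRUE)
  structure(list(ld_top = unname(ld_top), ld_nontop_mean = ld_nontop,
                 D = D, p_supra = p_supra, p_sub = p_sub, label = label,
                 top = top, reason = NULL),
            class = "supralinearity_result")
}

#' @export
print.supralinearity_result <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat(sprintf("Supra-linearity test: ns (%s)\n", x$reason))
  } else {
    cat(sprintf(
      "Supra-linearity test: %s (D = %.4g, p_supra = %.4g, p_sub = %.4g)\n",
      x$label, x$D, x$p_supra, x$p_sub))
  }
  invisible(x)
}
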