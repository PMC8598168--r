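#' Smoothed-ReLU static nonlinearity
#'
#' The static nonlinearity of the linear-nonlinear tuning model: a rectified
#' linear function convolved with a unit-standard-deviation Gaussian,
#'
#' \deqn{f(x) = \frac{x}{2}\left(1 + \mathrm{erf}(x/\sqrt{2})\right) +
#'   \frac{1}{\sqrt{2\pi}} e^{-x^2/2},}
#'
#' which is algebraically identical to `x * pnorm(x) + dnorm(x)` (the mean of
#' a rectified Gaussian with mean `x` and unit variance). It is strictly
#' increasing, convex, positive everywhere, and asymptotes to `max(0, x)`.
#'
#' @param x numeric vector.
#' @return `f(x)`, same shape as `x`.
#' @examples
#' static_nonlinearity(0)  # 1/sqrt(2*pi)
#' @export
static_nonlinearity <- function(x) {
  x * stats::pnorm(x) + stats::dnorm(x)
}

#' Predicted tuning curve of an LN neuron
#'
#' Evaluates `a * f(X w + h)` for every stimulus row of the design matrix,
#' where `f` is [static_nonlinearity()]. Noise is excluded.
#'
#' @param params list or `ln_params` with elements `w` (length-n weight
#'   vector), `h` (baseline drive) and `a` (amplitude, >= 0).
#' @param design binary design matrix from [design_matrix()].
#' @return numeric vector, one prediction per design row.
#' @export
ln_predict <- function(params, design) {
  stopifnot(length(params$w) == ncol(design))
  as.numeric(params$a * static_nonlinearity(design %*% params$w + params$h))
}

#' Construct LN parameters
#'
#' @param w element weights.
#' @param h baseline drive.
#' @param a response amplitude (>= 0).
#' @param noise_sd trial-to-trial Gaussian noise SD (simulation only, not a
#'   fitted parameter).
#' @return an object of class `"ln_params"`.
#' @export
ln_params <- function(w, h = 0, a = 1, noise_sd = 0) {
  stopifnot(is.numeric(w), is.finite(h), is.finite(a), a >= 0, noise_sd >= 0)
  structure(list(w = as.numeric(w), h = as.numeric(h), a = as.numeric(a),
                 noise_sd = as.numeric(noise_sd)), class = "ln_params")
}

#' Fit the 7-parameter LN tuning model
#'
#' Fits `r_s = a f(sum_j w_j x_sj + h)` to a measured tuning curve by
#' minimizing squared error with bounded quasi-Newton (L-BFGS-B), with
#' multiple restarts around an OLS initialization of the weights. With five
#' elements this is the 7-parameter model (five weights, baseline `h`,
#' amplitude `a`).
#'
#' @param train_tuning numeric tuning curve, one value per design row
#'   (non-finite entries are dropped from the objective; at least
#'   `ncol(design) + 2` finite values are required).
#' @param design binary design matrix ([design_matrix()]).
#' @param n_restarts number of random restarts (>= 1). `single_start = TRUE`
#'   forces the minimal single-start procedure.
#' @param seed optional RNG seed for restart jitter.
#' @param single_start if `TRUE`, use one deterministic start only.
#' @return An object of class `"ln_fit"`: `params` (`ln_params`),
#'   `train_sse`, `fitted`, `observed`, `design`, `converged`,
#'   `n_restarts_used`.
#' @export
fit_ln <- function(train_tuning, design, n_restarts = 10, seed = NULL,
                   single_start = FALSE) {
  ok <- is.finite(train_tuning)
  p <- ncol(design)
  if (sum(ok) < p + 2)
    stop(sprintf("need at least %d finite tuning values to fit %d parameters",
                 p + 2, p + 2))
  y <- train_tuning[ok]
  X <- design[ok, , drop = FALSE]
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  obj <- function(par) {
    pred <- par[p + 2L] * static_nonlinearity(X %*% par[seq_len(p)] + par[p + 1L])
    sum((pred - y)^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; h <- par[p + 1L]; a <- par[p + 2L]
    z <- as.numeric(X %*% w + h)
    fz <- static_nonlinearity(z)
    r <- 2 * (a * fz - y)
    dfdz <- stats::pnorm(z)          # f'(z) = Phi(z)
    c(crossprod(X, r * a * dfdz), sum(r * a * dfdz), sum(r * fz))
  }

  # OLS initialization of the weights (identity-nonlinearity approximation)
  ols <- tryCatch(stats::lm.fit(cbind(1, X), y)$coefficients,
                  error = function(e) rep(0, p + 1))
  ols[!is.finite(ols)] <- 0
  a0 <- max(max(y, na.rm = TRUE), 1e-3)
  starts <- list(c(ols[-1] / a0, -1, a0),
                 c(ols[-1] / a0, 0, a0),
                 c(rep(0, p), -2, a0))
  if (isTRUE(single_start)) {
    starts <- starts[1]
  } else {
    n_extra <- max(0L, as.integer(n_restarts) - length(starts))
    for (i in seq_len(n_extra))
      starts[[length(starts) + 1L]] <-
        c(ols[-1] / a0 + stats::rnorm(p, 0, 0.5 + 0.5 * i / n_extra),
          stats::runif(1, -3, 0.5), a0 * stats::runif(1, 0.5, 2))
    starts <- starts[seq_len(max(1L, as.integer(n_restarts)))]
  }

  best <- NULL
  n_used <- 0L
  for (st in starts) {
    n_used <- n_used + 1L
    res <- tryCatch(
      stats::optim(st, obj, gr = grad, method = "L-BFGS-B",
                   lower = c(rep(-Inf, p + 1L), 0),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, train_sse = NA_real_,
                          fitted = NULL, observed = train_tuning,
                          design = design, converged = FALSE,
                          n_restarts_used = n_used), class = "ln_fit"))
  }
  par <- best$par
  params <- ln_params(w = par[seq_len(p)], h = par[p + 1L], a = par[p + 2L])
  fitted <- ln_predict(params, design)
  structure(list(params = params, train_sse = best$value, fitted = fitted,
                 observed = train_tuning, design = design,
                 converged = TRUE, n_restarts_used = n_used),
            class = "ln_fit")
}

#' @export
print.ln_fit <- function(x, ...) {
  if (!x$converged) {
    cat("LN tuning model fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("LN tuning model fit (%d parameters)\n",
              length(x$params$w) + 2L))
  print(round(coef(x), 4))
  cat(sprintf("training SSE: %.4g\n", x$train_sse))
  invisible(x)
}

#' @export
coef.ln_fit <- function(object, ...) {
  p <- object$params
  stats::setNames(c(p$w, p$h, p$a),
                  c(paste0("w_", colnames(object$design)), "h", "a"))
}

#' @export
predict.ln_fit <- function(object, design = object$design, ...) {
  ln_predict(object$params, design)
}

#' @export
residuals.ln_fit <- function(object, ...) {
  object$observed - object$fitted
}

#' @export
summary.ln_fit <- function(object, ...) {
  r2 <- r_squared(object$fitted, object$observed)
  structure(list(fit = object, train_r2 = r2), class = "summary.ln_fit")
}

#' @export
print.summary.ln_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("training R^2: %.4f\n", x$train_r2))
  invisible(x)
}

#' Simulate tuning curves from a fitted LN model
#'
#' Draws `nsim` noisy tuning curves `a f(Xw + h) + eps` with i.i.d. Gaussian
#' noise of standard deviation `noise_sd` per condition.
#'
#' @param object an `ln_fit`.
#' @param nsim number of simulated curves.
#' @param seed optional RNG seed.
#' @param noise_sd noise SD (defaults to the residual SD of the fit).
#' @param ... unused.
#' @return matrix, conditions x `nsim`.
#' @export
simulate.ln_fit <- function(object, nsim = 1, seed = NULL,
                            noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd))
    noise_sd <- stats::sd(residuals(object), na.rm = TRUE)
  mu <- object$fitted
  matrix(mu, length(mu), nsim) +
    matrix(stats::rnorm(length(mu) * nsim, 0, noise_sd), length(mu), nsim)
}

#' @export
plot.ln_fit <- function(x, ...) {
  graphics::plot(x$observed, x$fitted,
                 xlab = "observed tuning", ylab = "LN model prediction", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Oracle model prediction
#'
#' The oracle comparator has one free parameter per stimulus condition (31
#' for five elements): its prediction is the training tuning curve itself.
#'
#' @param train_tuning numeric training tuning curve.
#' @return `train_tuning`, unchanged.
#' @export
oracle_predict <- function(train_tuning) train_tuning

#' Coefficient of determination on held-out data
#'
#' `R^2 = 1 - SSE/SST` with `SST` taken about the mean of `test`; computed
#' over conditions finite in both vectors. May be negative (a model worse
#' than the test mean); it is deliberately not clipped.
#'
#' @param pred model predictions.
#' @param test held-out measured tuning curve.
#' @return scalar R^2, or `NA` (with a `"reason"` attribute) if fewer than 3
#'   shared finite values or zero test variance.
#' @export
r_squared <- function(pred, test) {
  ok <- is.finite(pred) & is.finite(test)
  if (sum(ok) < 3)
    return(structure(NA_real_, reason = "fewer than 3 shared finite values"))
  sst <- sum((test[ok] - mean(test[ok]))^2)
  if (sst == 0)
    return(structure(NA_real_, reason = "zero variance in test data"))
  1 - sum((pred[ok] - test[ok])^2) / sst
}

#' Compare LN model and oracle on held-out R^2
#'
#' For neurons whose oracle test-set R^2 exceeds `oracle_r2_thresh`, computes
#' per-neuron `delta R^2 = R^2(LN) - R^2(oracle)` and a two-sided Wilcoxon
#' signed-rank test of whether the LN model outperforms the oracle (a
#' noise-ceiling comparator that copies the training curve verbatim).
#'
#' @param r2_glm numeric vector of LN-model test R^2, one per neuron.
#' @param r2_oracle numeric vector of oracle test R^2, same length.
#' @param oracle_r2_thresh inclusion gate on oracle test R^2 (default 0.5).
#' @return list with `delta_r2` (per passing neuron), `n`, `median_delta`,
#'   and `p` (Wilcoxon signed-rank, `NA` with fewer than 6 passing neurons).
#' @export
compare_models <- function(r2_glm, r2_oracle, oracle_r2_thresh = 0.5) {
  stopifnot(length(r2_glm) == length(r2_oracle))
  pass <- is.finite(r2_glm) & is.finite(r2_oracle) &
    r2_oracle > oracle_r2_thresh
  delta <- r2_glm[pass] - r2_oracle[pass]
  out <- list(delta_r2 = delta, n = sum(pass),
              median_delta = stats::median(delta),
              oracle_r2_thresh = oracle_r2_thresh, p = NA_real_)
  if (sum(pass) >= 6) {
    out$p <- stats::wilcox.test(delta, exact = FALSE)$p.value
  } else {
    warning("fewer than 6 neurons pass the oracle R^2 threshold; ",
            "descriptive output only")
  }
  out
}
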