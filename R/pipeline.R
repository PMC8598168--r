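#' Configuration of a full pipeline run
#'
#' Bundles stage parameters for an end-to-end reproducible run. All fields
#' are serializable; the resolved configuration (seed included) is written
#' next to every run's outputs.
#'
#' @param session a [session_config()] for a synthetic session, or a path to
#'   a session directory written by [write_session()].
#' @param out_dir output directory.
#' @param seed global seed.
#' @param signal_kind `"dff"` (stimulus-window mean dF/F) or `"events"`
#'   (deconvolved event rate).
#' @param state_mode `"running"`, `"stationary"` or `"none"`.
#' @param scheme cross-validation scheme, `"halves"` or `"thirds"`.
#' @param r_thresh reliability gate.
#' @param alpha FDR level for responsiveness.
#' @param n_boot bootstrap replicates for tuning CIs.
#' @param run_surrogates run the surrogate control battery?
#' @param fit_ln_models fit the LN/oracle model comparison?
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(session = session_config(), out_dir = tempfile("run"),
                       seed = 1L, signal_kind = c("dff", "events"),
                       state_mode = "running",
                       scheme = c("halves", "thirds"), r_thresh = 0.5,
                       alpha = 0.05, n_boot = 500, run_surrogates = FALSE,
                       fit_ln_models = TRUE) {
  signal_kind <- match.arg(signal_kind)
  scheme <- match.arg(scheme)
  if (!state_mode %in% c("running", "stationary", "none"))
    stop("invalid config field 'state_mode'")
  if (!(is.numeric(r_thresh) && length(r_thresh) == 1))
    stop("invalid config field 'r_thresh'")
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("invalid config field 'alpha'")
  structure(list(session = session, out_dir = out_dir,
                 seed = as.integer(seed), signal_kind = signal_kind,
                 state_mode = state_mode, scheme = scheme,
                 r_thresh = r_thresh, alpha = alpha,
                 n_boot = as.integer(n_boot),
                 run_surrogates = isTRUE(run_surrogates),
                 fit_ln_models = isTRUE(fit_ln_models)),
            class = "run_config")
}

write_tsv_out <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess (neuropil correction, catch-ITI
#' dF/F, optional deconvolution) -> per-trial responses with state and
#' outlier filtering -> responsiveness and classification -> cross-validated
#' population tuning and linear-difference matrices with the sorted-LD
#' profile -> LN-vs-oracle model comparison -> optional surrogate battery.
#' Every artifact is written to `cfg$out_dir` as TSV/JSON, stamped with the
#' seed; a failure in any stage aborts with the stage name while preserving
#' partial outputs. Re-running with the same configuration and seed
#' reproduces the outputs byte for byte.
#'
#' @param cfg a [run_config()].
#' @return the output directory, invisibly; the assembled results are
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  res <- list(seed = cfg$seed)
  jsonlite::write_json(
    c(unclass(cfg)[setdiff(names(cfg), "session")],
      list(session = if (is.character(cfg$session)) cfg$session
           else unclass(cfg$session))),
    file.path(cfg$out_dir, "config_resolved.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  session <- stage("simulate", {
    if (is.character(cfg$session)) read_session(cfg$session)
    else { s <- cfg$session; s$seed <- cfg$seed
           simulate_session(do.call(session_config, unclass(s))) }
  })
  resp <- stage("preprocess", {
    corrected <- neuropil_correct(session$raw)
    dff <- dff_catch_baseline(corrected, session$trial_table)
    traces <- if (cfg$signal_kind == "events")
      deconvolve(dff, kernel_tau_s = session$config$kernel_tau_s) else dff
    trial_responses(traces, session$trial_table, session$space,
                    window_s = session$config$stim_duration_s)
  })
  resp <- stage("respond", filter_responses(resp, mode = cfg$state_mode))
  sig <- stage("respond", responsiveness(resp, alpha = cfg$alpha))
  res$significance <- sig
  space <- session$space
  conds <- which(!space$is_catch)
  write_tsv_out(data.frame(neuron = rep(seq_len(nrow(sig$p)),
                                        each = length(conds)),
                           bits = rep(space$bits[conds], nrow(sig$p)),
                           mean_response = as.vector(t(sig$mean_response)),
                           p = as.vector(t(sig$p)),
                           significant = as.vector(t(sig$significant))),
                file.path(cfg$out_dir, "significance.tsv"))
  write_tsv_out(data.frame(neuron = seq_along(sig$class),
                           responsive = sig$responsive, class = sig$class),
                file.path(cfg$out_dir, "classification.tsv"))

  pm <- stage("tune", population_matrices(resp, scheme = cfg$scheme,
                                          r_thresh = cfg$r_thresh,
                                          seed = cfg$seed))
  res$matrices <- pm
  for (kind in c("tuning", "ld")) {
    m <- pm[[kind]]$matrix
    write_tsv_out(cbind(data.frame(neuron = pm[[kind]]$neurons,
                                   preferred_bits =
                                     space$bits[pm[[kind]]$preferred]),
                        as.data.frame(m)),
                  file.path(cfg$out_dir,
                            sprintf("population_%s.tsv", kind)))
  }
  res$sorted_ld <- stage("tune", {
    parts <- pm$tuning$parts
    train_parts <- if (cfg$scheme == "thirds") 1:2 else 1L
    n <- nrow(resp$values)
    train_m <- matrix(NA_real_, n, length(conds))
    ld_m <- matrix(NA_real_, n, length(multi_conditions(space)))
    for (i in pm$tuning$neurons) {
      tr <- tuning_curve(resp, i, n_boot = 0,
                         trials = which(parts %in% train_parts))
      te <- tuning_curve(resp, i, n_boot = 0,
                         trials = which(parts == max(parts)))
      train_m[i, ] <- tr$values
      ld_m[i, ] <- linear_difference(te)$ld
    }
    sl <- sorted_linear_difference(train_m[pm$tuning$neurons, , drop = FALSE],
                                   ld_m[pm$tuning$neurons, , drop = FALSE],
                                   space)
    write_tsv_out(data.frame(rank = seq_along(sl$mean_ld),
                             mean_ld = sl$mean_ld),
                  file.path(cfg$out_dir, "sorted_ld.tsv"))
    sl
  })

  if (cfg$fit_ln_models) {
    res$model_comparison <- stage("fit-ln", {
      parts <- pm$tuning$parts
      X <- design_matrix(space)
      r2g <- r2o <- rep(NA_real_, nrow(resp$values))
      for (i in seq_len(nrow(resp$values))) {
        tr <- tryCatch(tuning_curve(resp, i, n_boot = 0,
                                    trials = which(parts == 1)),
                       error = function(e) NULL)
        te <- tryCatch(tuning_curve(resp, i, n_boot = 0,
                                    trials = which(parts != 1)),
                       error = function(e) NULL)
        if (is.null(tr) || is.null(te)) next
        fit <- fit_ln(tr$values, X, n_restarts = 5, seed = cfg$seed + i)
        if (!fit$converged) next
        r2g[i] <- r_squared(fit$fitted, te$values)
        r2o[i] <- r_squared(oracle_predict(tr$values), te$values)
      }
      cmpr <- suppressWarnings(compare_models(r2g, r2o))
      jsonlite::write_json(list(median_delta_r2 = cmpr$median_delta,
                                n = cmpr$n, p = cmpr$p,
                                oracle_r2_thresh = cmpr$oracle_r2_thresh,
                                seed = cfg$seed),
                           file.path(cfg$out_dir, "model_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      c(cmpr, list(r2_glm = r2g, r2_oracle = r2o))
    })
  }

  if (cfg$run_surrogates) {
    res$surrogates <- stage("surrogate", {
      parts <- pm$tuning$parts
      np <- max(parts)
      n <- nrow(resp$values)
      base <- array(NA_real_, c(n, length(conds), np))
      for (i in seq_len(n)) for (p in seq_len(np)) {
        tc <- tryCatch(tuning_curve(resp, i, n_boot = 0,
                                    trials = which(parts == p)),
                       error = function(e) NULL)
        if (!is.null(tc)) base[i, , p] <- tc$values
      }
      rep <- surrogate_battery(base, space, seed = cfg$seed)
      jsonlite::write_json(
        lapply(rep, function(r) r[c("enrichment", "frac_supra_flagged",
                                    "n_gated",
                                    "per_session_top_vs_nontop")]),
        file.path(cfg$out_dir, "surrogate_report.json"),
        auto_unbox = TRUE, digits = NA)
      rep
    })
  }
  res$session <- session
  res$responses <- resp
  structure(invisible(cfg$out_dir), results = res)
}

#' Render a summary report for a pipeline run
#'
#' Renders the population tuning and linear-difference heatmaps, the
#' rank-sorted linear-difference profile, and (when present) the
#' supra-vs-sub scatter and surrogate panels as PNG figures, plus a plain
#' text summary. Missing stage outputs produce a partial report with
#' warnings rather than an error.
#'
#' @param out_dir a directory produced by [run_pipeline()].
#' @return paths of the written report files, invisibly.
#' @export
report <- function(out_dir) {
  written <- character(0)
  emit <- function(file, expr) {
    grDevices::png(file.path(out_dir, file), width = 700, height = 500)
    on.exit(grDevices::dev.off())
    expr
    written <<- c(written, file.path(out_dir, file))
  }
  pm_file <- file.path(out_dir, "population_tuning.tsv")
  summary_lines <- c(sprintf("Pipeline report for %s", out_dir))
  if (file.exists(pm_file)) {
    pm <- utils::read.delim(pm_file)
    m <- as.matrix(pm[, -(1:2), drop = FALSE])
    if (nrow(m) > 0) {
      emit("population_tuning.png",
           graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                           axes = FALSE, main = "Cross-validated tuning",
                           xlab = "condition", ylab = "neuron"))
      summary_lines <- c(summary_lines,
                         sprintf("%d neurons pass the reliability gate",
                                 nrow(m)))
    } else {
      summary_lines <- c(summary_lines, "zero passing neurons")
    }
  } else warning("population matrix output missing; partial report")
  ld_file <- file.path(out_dir, "population_ld.tsv")
  if (file.exists(ld_file)) {
    ld <- utils::read.delim(ld_file)
    m <- as.matrix(ld[, -(1:2), drop = FALSE])
    if (nrow(m) > 0)
      emit("population_ld.png",
           graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                           axes = FALSE, main = "Normalized linear difference",
                           xlab = "condition", ylab = "neuron"))
  }
  sl_file <- file.path(out_dir, "sorted_ld.tsv")
  if (file.exists(sl_file)) {
    sl <- utils::read.delim(sl_file)
    emit("sorted_ld.png", {
      graphics::plot(sl$rank, sl$mean_ld, type = "b",
                     xlab = "stimulus rank (train partition)",
                     ylab = "mean linear difference (test partition)")
      graphics::abline(h = 0, lty = 2)
    })
  }
  mc_file <- file.path(out_dir, "model_comparison.json")
  if (file.exists(mc_file)) {
    mc <- jsonlite::read_json(mc_file)
    summary_lines <- c(summary_lines,
                       sprintf("LN vs oracle: median dR2 = %.4g (n = %d, p = %.3g)",
                               mc$median_delta_r2, mc$n,
                               if (is.null(mc$p)) NA else mc$p))
  }
  sr_file <- file.path(out_dir, "surrogate_report.json")
  if (file.exists(sr_file)) {
    sr <- jsonlite::read_json(sr_file)
    for (mode in names(sr))
      summary_lines <- c(summary_lines,
                         sprintf("surrogate %s: enrichment %.4f, supra rate %.3f",
                                 mode, sr[[mode]]$enrichment,
                                 sr[[mode]]$frac_supra_flagged))
  }
  writeLines(summary_lines, file.path(out_dir, "report.txt"))
  invisible(c(written, file.path(out_dir, "report.txt")))
}
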