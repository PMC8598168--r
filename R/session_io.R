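#' Write a synthetic session to disk
#'
#' Serializes a session as a directory of plain-text files: a JSON manifest
#' (`session.json`, schema-versioned, holding the full configuration and the
#' seed), the trial table (`trials.tsv`), per-neuron ground truth
#' (`truth.tsv` with LN parameters and the tabulated tuning vector), true
#' trial amplitudes (`amplitudes.tsv`) and, when present, the raw ROI and
#' neuropil trace matrices (`R.tsv`, `N.tsv`, neuron x time). The round trip
#' through [read_session()] is lossless (bit-exact for integers and flags,
#' within 1e-12 relative error for floats).
#'
#' @param session a `synthetic_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema_version = 1L,
                   config = unclass(session$config),
                   element_labels = session$space$element_labels,
                   has_traces = !is.null(session$raw))
  jsonlite::write_json(manifest, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv <- function(x, file)
    utils::write.table(format(as.data.frame(x), digits = 17, trim = TRUE,
                              scientific = TRUE),
                       file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  utils::write.table(session$trial_table, file.path(path, "trials.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_cond <- sum(!session$space$is_catch)
  truth <- do.call(rbind, lapply(session$truth, function(nr) {
    w <- rep(NA_real_, session$config$n_elements)
    h <- NA_real_; a <- NA_real_
    if (!is.null(nr$params)) { w <- nr$params$w; h <- nr$params$h; a <- nr$params$a }
    row <- data.frame(kind = nr$kind, h = h, a = a,
                      trial_noise_sd = nr$trial_noise_sd,
                      catch_mean = nr$catch_mean,
                      contamination_k_true = nr$contamination_k_true)
    for (j in seq_along(w)) row[[paste0("w", j)]] <- w[j]
    for (s in seq_len(n_cond)) row[[paste0("tuning", s)]] <- nr$tuning[s]
    row
  }))
  write_tsv(truth, "truth.tsv")
  write_tsv(session$amplitudes, "amplitudes.tsv")
  if (!is.null(session$raw)) {
    write_tsv(session$raw$R, "R.tsv")
    write_tsv(session$raw$N, "N.tsv")
  }
  invisible(path)
}

#' Read a synthetic session from disk
#'
#' Inverse of [write_session()]. Fails with an informative error naming the
#' missing file or an unsupported schema version.
#'
#' @param path session directory.
#' @return a `synthetic_session`.
#' @export
read_session <- function(path) {
  need <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f))
      stop(sprintf("session at '%s' is missing required file '%s'",
                   path, file))
    f
  }
  manifest <- jsonlite::read_json(need("session.json"), simplifyVector = TRUE)
  if (is.null(manifest$schema_version) || manifest$schema_version != 1L)
    stop(sprintf("unsupported session schema version '%s' (expected 1)",
                 manifest$schema_version))
  cfg <- do.call(session_config, manifest$config)
  tt <- utils::read.delim(need("trials.tsv"))
  truth_df <- utils::read.delim(need("truth.tsv"))
  amp <- as.matrix(utils::read.delim(need("amplitudes.tsv")))
  dimnames(amp) <- NULL
  n_el <- cfg$n_elements
  n_cond <- 2^n_el - 1
  pop <- lapply(seq_len(nrow(truth_df)), function(i) {
    r <- truth_df[i, ]
    w <- as.numeric(r[paste0("w", seq_len(n_el))])
    params <- if (r$kind == "tabulated") NULL
              else ln_params(w = w, h = r$h, a = r$a)
    list(kind = r$kind, params = params,
         tuning = as.numeric(r[paste0("tuning", seq_len(n_cond))]),
         catch_mean = r$catch_mean, trial_noise_sd = r$trial_noise_sd,
         contamination_k_true = r$contamination_k_true)
  })
  raw <- NULL
  if (isTRUE(manifest$has_traces)) {
    R <- as.matrix(utils::read.delim(need("R.tsv"))); dimnames(R) <- NULL
    N <- as.matrix(utils::read.delim(need("N.tsv"))); dimnames(N) <- NULL
    raw <- structure(list(R = R, N = N, frame_rate_hz = cfg$frame_rate_hz),
                     class = "raw_traces")
  }
  structure(list(config = cfg,
                 space = enumerate_conditions(n_el,
                   element_labels = manifest$element_labels),
                 truth = pop, trial_table = tt, amplitudes = amp, raw = raw),
            class = "synthetic_session")
}
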