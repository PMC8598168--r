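#' Enumerate the combinatorial stimulus space
#'
#' Builds the full set of stimulus conditions for an experiment in which each
#' stimulus is a non-empty subset of `n_elements` discrete elements (e.g. five
#' whiskers contacted by pistons, or five visual grating patches). For
#' `n_elements = 5` this yields the 31 possible combinations; an optional
#' catch (no-stimulus) condition is appended last.
#'
#' Conditions are ordered canonically: by subset size ascending, then
#' lexicographically on the sorted element indices. Element indices are
#' 0-based internally; `element_labels` are used for display.
#'
#' @param n_elements number of stimulus elements (1--16).
#' @param include_catch append a catch (empty) condition at the end?
#' @param element_labels optional character vector of length `n_elements`
#'   naming the elements; defaults to `C2, C1, B1, D1, gamma` for five
#'   elements and `E1, E2, ...` otherwise.
#' @return An object of class `"stimulus_space"`: a list with `n_elements`,
#'   `masks` (list of 0-based integer vectors, one per condition),
#'   `is_catch` (logical), `bits` (character bit-strings, element j present
#'   at position j+1), `size` (subset sizes) and `element_labels`.
#' @examples
#' sp <- enumerate_conditions(5)
#' sum(!sp$is_catch)  # 31
#' @export
enumerate_conditions <- function(n_elements = 5L, include_catch = TRUE,
                                 element_labels = NULL) {
  if (length(n_elements) != 1L || is.na(n_elements) ||
      n_elements < 1 || n_elements > 16 || n_elements != round(n_elements))
    stop("'n_elements' must be a single integer in 1..16")
  n <- as.integer(n_elements)
  if (is.null(element_labels)) {
    element_labels <- if (n == 5L) c("C2", "C1", "B1", "D1", "gamma")
                      else paste0("E", seq_len(n))
  }
  if (length(element_labels) != n)
    stop("'element_labels' must have length n_elements")
  masks <- list()
  for (k in seq_len(n)) {
    combs <- utils::combn(n, k) - 1L     # 0-based, columns already lexicographic
    masks <- c(masks, lapply(seq_len(ncol(combs)), function(j) combs[, j]))
  }
  is_catch <- rep(FALSE, length(masks))
  if (isTRUE(include_catch)) {
    masks <- c(masks, list(integer(0)))
    is_catch <- c(is_catch, TRUE)
  }
  bits <- vapply(masks, mask_bits, character(1), n = n)
  structure(list(
    n_elements = n,
    masks = masks,
    is_catch = is_catch,
    bits = bits,
    size = lengths(masks),
    element_labels = element_labels
  ), class = "stimulus_space")
}

mask_bits <- function(mask, n) {
  b <- rep("0", n)
  b[mask + 1L] <- "1"
  paste(b, collapse = "")
}

#' @export
print.stimulus_space <- function(x, ...) {
  cat(sprintf("Stimulus space: %d elements (%s), %d conditions%s\n",
              x$n_elements, paste(x$element_labels, collapse = ", "),
              length(x$masks),
              if (any(x$is_catch)) " (incl. catch)" else ""))
  invisible(x)
}

#' Condition labels
#'
#' Human-readable labels (joined element labels, or `"catch"`).
#' @param space a `stimulus_space`.
#' @return character vector, one label per condition.
#' @export
condition_labels <- function(space) {
  vapply(seq_along(space$masks), function(i) {
    if (space$is_catch[i]) "catch"
    else paste(space$element_labels[space$masks[[i]] + 1L], collapse = "+")
  }, character(1))
}

#' Look up a condition index by element mask
#'
#' @param space a `stimulus_space`.
#' @param mask 0-based integer vector of element indices (empty for catch).
#' @return integer condition index within `space`.
#' @export
condition_index <- function(space, mask) {
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) == 0L) {
    i <- which(space$is_catch)
    if (length(i) != 1L) stop("no catch condition in stimulus space")
    return(i)
  }
  bits <- mask_bits(mask, space$n_elements)
  i <- which(space$bits == bits & !space$is_catch)
  if (length(i) != 1L) stop("condition not found in stimulus space")
  i
}

#' Binary design matrix of the stimulus space
#'
#' One row per non-catch condition, one column per element; entry (s, j) is 1
#' if element j is part of stimulus s and 0 otherwise.
#'
#' @param space a `stimulus_space`.
#' @return binary matrix with condition bit-strings as row names and element
#'   labels as column names.
#' @export
design_matrix <- function(space) {
  stopifnot(inherits(space, "stimulus_space"))
  keep <- !space$is_catch
  if (!any(keep)) stop("stimulus space has no non-catch conditions")
  x <- t(vapply(space$masks[keep], function(m) {
    row <- numeric(space$n_elements)
    row[m + 1L] <- 1
    row
  }, numeric(space$n_elements)))
  dimnames(x) <- list(space$bits[keep], space$element_labels)
  x
}

#' Singleton components of a condition
#'
#' Indices (within `space`) of the single-element conditions composing a
#' multi-element condition; used by the linear-difference statistic.
#'
#' @param space a `stimulus_space`.
#' @param i condition index.
#' @return integer vector of singleton condition indices, canonical order.
#' @export
singleton_components <- function(space, i) {
  stopifnot(inherits(space, "stimulus_space"))
  if (space$is_catch[i]) stop("catch condition has no singleton components")
  vapply(sort(space$masks[[i]]), function(e) condition_index(space, e),
         integer(1))
}

#' Indices of singleton / multi-element conditions
#' @param space a `stimulus_space`.
#' @return integer vector of condition indices.
#' @export
singleton_conditions <- function(space) which(space$size == 1L & !space$is_catch)

#' @rdname singleton_conditions
#' @export
multi_conditions <- function(space) which(space$size >= 2L & !space$is_catch)
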