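# Matrix balancing (iterative correction) per replicate and quantile
# normalization across replicates, yielding Observed Interaction Frequency
# matrices comparable across conditions.

#' ICE balancing (iterative correction) of a contact matrix
#'
#' Imakaev-style iterative correction: repeatedly divide the matrix by the
#' outer product of per-row factors proportional to the informative row
#' sums, until all informative row sums agree with their mean to within
#' `tol` (relative). Diagonal and near-diagonal pixels (`|i - j| <
#' min_separation`) are excluded from balancing as non-informative, as are
#' rows with no informative mass. Biases are normalized to geometric mean 1,
#' making the balanced matrix unique.
#'
#' @param cm a [contact_matrix()] (symmetric, non-negative).
#' @param tol convergence tolerance on the maximum relative deviation of row
#'   sums from their mean.
#' @param max_iter iteration cap.
#' @param min_separation pixels with `|i - j|` below this (in axis units)
#'   are excluded; default 1 excludes the diagonal only.
#' @return object of class `balanced_matrix`: list with `matrix` (balanced
#'   [contact_matrix()]), `biases` (NA for excluded rows), `n_iterations`,
#'   `converged`, `included` (logical per row).
#' @export
ice_balance <- function(cm, tol = 1e-8, max_iter = 500L, min_separation = 1L) {
  v <- cm$values
  n <- nrow(v)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  mask <- cm$informative & sep >= min_separation
  raw <- ifelse(mask, v, 0)
  raw[is.na(raw)] <- 0
  included <- rowSums(raw) > 0 & rowSums(mask) > 0
  if (!any(included)) {
    ls_stop("no rows with informative mass to balance", "loopscore_validation_error")
  }
  mask[!included, ] <- FALSE
  mask[, !included] <- FALSE
  raw[!mask] <- 0
  b <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    V <- raw / outer(b, b)
    s <- rowSums(V)[included]
    m <- mean(s)
    dev <- max(abs(s / m - 1))
    if (dev < tol) {
      converged <- TRUE
      break
    }
    s_full <- rowSums(V)
    b[included] <- b[included] * (s_full[included] / m)
  }
  # pin the scale: biases have geometric mean 1 over included rows
  b[included] <- b[included] / exp(mean(log(b[included])))
  b[!included] <- NA_real_
  V <- cm$values / outer(b, b)
  V[!mask] <- NA_real_
  out <- contact_matrix(V, mask, cm$axis, cm$level)
  structure(list(matrix = out, biases = b, n_iterations = iter,
                 converged = converged, included = included),
            class = "balanced_matrix")
}

#' @export
print.balanced_matrix <- function(x, ...) {
  cat(sprintf("<balanced_matrix> %d rows (%d balanced); %d iterations; converged: %s\n",
              nrow(x$matrix$values), sum(x$included), x$n_iterations, x$converged))
  invisible(x)
}

#' Quantile-normalize contact matrices across replicates
#'
#' The informative upper-triangle values of each matrix (restricted to the
#' intersection of the informative masks, so the rank machinery is
#' well-defined) are quantile normalized: each value is replaced by the mean
#' across matrices of the values sharing its rank, ties receiving the
#' average of their rank-means. Afterwards the sorted value vectors of all
#' matrices are identical. Delegates to `limma::normalizeQuantiles`.
#'
#' Tied values: with `ties = "sequential"` (the default, used by the
#' pipeline) ties are broken by position, so every matrix ends up with
#' exactly the same multiset of values — the sorted value vectors are
#' bitwise identical even when bins structurally duplicate each other
#' (adjacent bins whose 12 kb windows capture identical fragment sets).
#' With `ties = "average"` tied values instead receive the average of their
#' rank-means (the rank-averaging convention); tied inputs then map to tied
#' outputs, at the cost of exact distribution sharing across replicates.
#'
#' @param cms list of >= 2 [contact_matrix()] objects on the same axis.
#' @param ties tie-handling convention, see Details.
#' @return list of quantile-normalized [contact_matrix()] objects on the
#'   common informative mask.
#' @export
quantile_normalize <- function(cms, ties = c("sequential", "average")) {
  ties <- match.arg(ties)
  if (length(cms) < 2L) {
    ls_stop("quantile normalization needs >= 2 matrices", "loopscore_parameter_error")
  }
  dims <- vapply(cms, function(x) nrow(x$values), integer(1L))
  if (length(unique(dims)) != 1L) {
    ls_stop("matrices must share an axis", "loopscore_validation_error")
  }
  common <- Reduce(`&`, lapply(cms, `[[`, "informative"))
  diag(common) <- FALSE # normalization operates on off-diagonal pixels
  up <- which(common & upper.tri(common), arr.ind = TRUE)
  if (nrow(up) == 0L) {
    ls_stop("informative masks are disjoint", "loopscore_validation_error")
  }
  X <- vapply(cms, function(x) x$values[up], numeric(nrow(up)))
  Xn <- limma::normalizeQuantiles(X, ties = (ties == "average"))
  lapply(seq_along(cms), function(k) {
    v <- matrix(NA_real_, dims[1L], dims[1L])
    v[up] <- Xn[, k]
    v[up[, c(2L, 1L), drop = FALSE]] <- Xn[, k]
    contact_matrix(v, common, cms[[k]]$axis, cms[[k]]$level)
  })
}
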