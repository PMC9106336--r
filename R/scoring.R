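# Donut-background expected model, background-normalized ratios, logistic-fit
# p-values, -10*log2(p) interaction scores, and loop-pixel quantification.

# Distance-decay reference: per-|i - j|-diagonal summary of the observed
# values over informative pixels, used to weight the donut ring. The median
# (default) is robust to enriched loop pixels, which make up a visible
# fraction of a diagonal on region-scale (hundreds of bins) matrices; the
# mean is available for large matrices where loops are negligible.
decay_reference <- function(cm, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  n <- nrow(cm$values)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  v <- cm$values[cm$informative]
  d <- sep[cm$informative]
  ref <- rep(NA_real_, n)
  agg <- tapply(v, d, f)
  ref[as.integer(names(agg)) + 1L] <- agg
  ref # ref[k] is the reference at separation k - 1
}

#' Donut-background expected model
#'
#' For each informative pixel (i, j), the expected value is the observed sum
#' over the donut ring (Chebyshev distance in `(p_excl, w]` around the
#' pixel, informative in-bounds cells only) divided by the corresponding
#' ring sum of a distance-decay reference and multiplied by the reference at
#' (i, j). The reference is a per-|i - j|-diagonal summary of the observed
#' values (median by default; see `decay_stat`). Pixels whose ring holds
#' fewer than `min_ring` informative members are undefined.
#'
#' @param cm balanced, normalized bin-level [contact_matrix()].
#' @param w donut half-width in bins.
#' @param p_excl excluded-center half-width in bins (`w > p_excl >= 1`).
#' @param min_ring minimum informative ring pixels for a defined expectation.
#' @param decay_stat per-diagonal summary used for the distance-decay
#'   reference: `"median"` (default, robust to enriched loop pixels on
#'   region-scale matrices) or `"mean"`.
#' @return object of class `expected_matrix`: list with `values` (matrix, NA
#'   where undefined), `w`, `p_excl`, `min_ring`, `ring_n`.
#' @export
donut_expected <- function(cm, w = 5L, p_excl = 2L, min_ring = 10L,
                           decay_stat = c("median", "mean")) {
  if (w <= p_excl || p_excl < 1L) {
    ls_stop("need donut width w > exclusion radius p_excl >= 1",
            "loopscore_parameter_error")
  }
  n <- nrow(cm$values)
  off <- expand.grid(di = -w:w, dj = -w:w)
  cheb <- pmax(abs(off$di), abs(off$dj))
  off <- as.matrix(off[cheb > p_excl & cheb <= w, , drop = FALSE])
  inf <- cm$informative
  O <- ifelse(inf, cm$values, 0)
  E0 <- decay_reference(cm, stat = decay_stat)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  E0mat <- matrix(E0[sep + 1L], n, n)
  E0m <- ifelse(inf, E0mat, 0)
  ring_obs <- offset_sum(O, off)
  ring_exp <- offset_sum(E0m, off)
  ring_n <- offset_sum(inf + 0, off)
  expected <- ring_obs / ring_exp * E0mat
  expected[!inf | ring_n < min_ring | ring_exp <= 0] <- NA_real_
  structure(list(values = expected, w = w, p_excl = p_excl,
                 min_ring = min_ring, ring_n = ring_n),
            class = "expected_matrix")
}

#' Background-normalize observed by expected
#'
#' @param observed bin-level [contact_matrix()].
#' @param expected matching [donut_expected()] result.
#' @return matrix of observed/expected ratios, NA where either is undefined.
#' @export
background_normalize <- function(observed, expected) {
  e <- expected$values
  if (!identical(dim(e), dim(observed$values))) {
    ls_stop("observed and expected have different axes", "loopscore_validation_error")
  }
  defined <- observed$informative & !is.na(e)
  if (any(e[defined] <= 0)) {
    ls_stop("expected <= 0 at a defined pixel (expected-matrix invariant violated)",
            "loopscore_internal_error")
  }
  ratio <- matrix(NA_real_, nrow(e), ncol(e))
  ratio[defined] <- observed$values[defined] / e[defined]
  ratio
}

#' Maximum-likelihood logistic fit
#'
#' Fits a logistic distribution to the pooled background-normalized ratios
#' of one matrix by maximum likelihood (via `MASS::fitdistr`), starting from
#' the method-of-moments estimates (location = mean, scale = sd * sqrt(3) /
#' pi).
#'
#' @param values numeric vector (>= 30 finite, not all equal).
#' @param log_scale fit on the natural log of (positive) values instead.
#' @return named numeric `c(location, scale)`.
#' @export
fit_logistic <- function(values, log_scale = FALSE) {
  x <- values[is.finite(values)]
  if (log_scale) x <- log(x[x > 0])
  if (length(x) < 30L) {
    ls_stop(sprintf("need >= 30 finite values for a logistic fit, got %d", length(x)),
            "loopscore_insufficient_data_error")
  }
  if (stats::sd(x) == 0) {
    ls_stop("degenerate logistic fit: all values equal", "loopscore_degenerate_fit_error")
  }
  start <- list(location = mean(x), scale = stats::sd(x) * sqrt(3) / pi)
  fit <- suppressWarnings(MASS::fitdistr(x, "logistic", start = start))
  est <- fit$estimate
  c(location = unname(est["location"]), scale = unname(est["scale"]))
}

#' P-values and Background-corrected Interaction Scores
#'
#' Upper-tail logistic survival p = 1 / (1 + exp((x - location) / scale)),
#' floored at `p_floor`; interaction score = -10 * log2(p). Score 0 at
#' p = 1, 10 at p = 0.5, 20 at p = 0.25.
#'
#' @param ratios matrix (or vector) of background-normalized ratios.
#' @param location,scale fitted logistic parameters (`scale > 0`).
#' @param p_floor lower bound on p (default 1e-12, capping scores near 398.6).
#' @param log_scale apply the fit on the log of the ratios (must match the
#'   scale the parameters were fitted on).
#' @return object of class `score_map`: list with `ratio`, `p_value`,
#'   `score`, `location`, `scale`.
#' @export
pvalues_and_scores <- function(ratios, location, scale, p_floor = 1e-12,
                               log_scale = FALSE) {
  stopifnot(scale > 0)
  x <- ratios
  if (log_scale) x <- log(x)
  p <- stats::plogis(x, location = location, scale = scale, lower.tail = FALSE)
  p <- pmax(p, p_floor)
  score <- -10 * log2(p)
  structure(list(ratio = ratios, p_value = p, score = score,
                 location = location, scale = scale),
            class = "score_map")
}

#' Score a normalized matrix against its donut expected model
#'
#' Convenience wrapper: background-normalize, fit the logistic null on the
#' pooled defined ratios, and convert to interaction scores.
#'
#' @inheritParams background_normalize
#' @inheritParams pvalues_and_scores
#' @return a `score_map`.
#' @export
score_matrix <- function(observed, expected, p_floor = 1e-12, log_scale = FALSE) {
  ratio <- background_normalize(observed, expected)
  fit <- fit_logistic(ratio[!is.na(ratio)], log_scale = log_scale)
  pvalues_and_scores(ratio, fit["location"], fit["scale"],
                     p_floor = p_floor, log_scale = log_scale)
}

# Bin indices of a matrix axis overlapping an anchor interval.
bins_overlapping <- function(cm, anchor) {
  which(overlaps(cm$axis, anchor[rep(1L, nrow(cm$axis)), , drop = FALSE]))
}

#' Quantify loop pixels between two anchors
#'
#' Mean of the informative pixel values over the rectangle (bins overlapping
#' `anchorA`) x (bins overlapping `anchorB`).
#'
#' @param cm bin-level [contact_matrix()].
#' @param anchorA,anchorB one-row interval data.frames.
#' @return list with `mean` (NA when the rectangle is fully non-informative)
#'   and `n_pixels`.
#' @export
quantify_loop_pixels <- function(cm, anchorA, anchorB) {
  ba <- bins_overlapping(cm, anchorA)
  bb <- bins_overlapping(cm, anchorB)
  if (length(ba) == 0L || length(bb) == 0L) {
    ls_stop("anchor maps to no bin on the matrix axis", "loopscore_validation_error")
  }
  rect <- cm$values[ba, bb, drop = FALSE]
  ok <- !is.na(rect)
  list(mean = if (any(ok)) mean(rect[ok]) else NA_real_, n_pixels = sum(ok))
}

#' Distance-corrected loop strength
#'
#' Mean of observed/expected over the anchor rectangle: loop strength
#' corrected for the distance-dependent background signal, comparable
#' between short- and long-range loops.
#'
#' @inheritParams quantify_loop_pixels
#' @param expected matching [donut_expected()] result.
#' @return list with `ratio` (NA when undefined on the whole rectangle) and
#'   `n_pixels`.
#' @export
distance_corrected_loop_strength <- function(cm, expected, anchorA, anchorB) {
  ba <- bins_overlapping(cm, anchorA)
  bb <- bins_overlapping(cm, anchorB)
  if (length(ba) == 0L || length(bb) == 0L) {
    ls_stop("anchor maps to no bin on the matrix axis", "loopscore_validation_error")
  }
  obs <- cm$values[ba, bb, drop = FALSE]
  e <- expected$values[ba, bb, drop = FALSE]
  ok <- !is.na(obs) & !is.na(e)
  list(ratio = if (any(ok)) mean(obs[ok] / e[ok]) else NA_real_,
       n_pixels = sum(ok))
}
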