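# Raw primer-pair counts -> binned relative interaction frequency:
# tally valid read pairs, remove PCR-bias outliers, convert to
# fragment-fragment counts, bin to the 4 kb grid with a 12 kb window.

#' Tally primer-pair read assignments into a primer-level contact matrix
#'
#' A read pair is tallied iff one end maps to a forward-sense primer
#' (FOR/LFOR) and the other to a reverse-sense primer (REV/LREV); all other
#' pairs are discarded and counted. Tallied + discarded equals the number of
#' input read pairs.
#'
#' @param assignments data.frame with columns `end1`, `end2` of primer ids.
#' @param design a `primer_design`.
#' @return primer-level [contact_matrix()] with attribute `discarded`.
#' @export
tally_pair_counts <- function(assignments, design) {
  pr <- design$primers
  n <- nrow(pr)
  i1 <- match(assignments$end1, pr$primer_id)
  i2 <- match(assignments$end2, pr$primer_id)
  if (anyNA(i1) || anyNA(i2)) {
    unknown <- unique(c(assignments$end1[is.na(i1)], assignments$end2[is.na(i2)]))
    ls_stop(paste0("unknown primer id(s): ", paste(unknown, collapse = ", ")),
            "loopscore_validation_error")
  }
  valid <- queryable_pair(pr$orientation[i1], pr$orientation[i2]) & i1 != i2
  v <- matrix(0, n, n)
  if (any(valid)) {
    ii <- pmin(i1[valid], i2[valid])
    jj <- pmax(i1[valid], i2[valid])
    tab <- table(factor(paste(ii, jj), levels = unique(paste(ii, jj))))
    key <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    idx <- cbind(as.integer(key[, 1L]), as.integer(key[, 2L]))
    v[idx] <- as.numeric(tab)
    v <- v + t(v)
  }
  fwd <- is_forward_sense(pr$orientation)
  queryable <- outer(fwd, fwd, FUN = xor)
  diag(queryable) <- FALSE
  v[!queryable] <- NA_real_
  cm <- contact_matrix(v, queryable, pr[, c("chrom", "start", "end")], "primer")
  attr(cm, "discarded") <- sum(!valid)
  cm
}

#' Remove PCR-bias outlier primer pairs
#'
#' A primer pair is removed when its count is at least `fold` times the
#' median of the 5x5 index window of the counts matrix centered on it
#' (center cell included; windows truncated at matrix edges). By default the
#' median is taken over the informative window cells only; set
#' `noninformative_as_zero = TRUE` to instead treat non-queryable window
#' cells as zeros. When the window median is zero it is replaced by
#' `zero_floor` (default 1), so isolated counts on a sparse background are
#' removed only beyond an absolute threshold. Decisions are made in a single
#' pass on the input matrix; both (i, j) and (j, i) are marked
#' non-informative.
#'
#' @param cm primer-level [contact_matrix()].
#' @param fold removal threshold (> 1); the study used 8 (100 for one
#'   lower-quality region), exposed per region.
#' @param half_window half-width of the median window (2 gives 5x5).
#' @param zero_floor replacement for a zero window median.
#' @param noninformative_as_zero include non-informative in-bounds window
#'   cells as zeros.
#' @return list with `matrix` (filtered contact matrix) and `removed`
#'   (data.frame `i`, `j`, `count`, `window_median`).
#' @export
remove_outliers <- function(cm, fold = 8, half_window = 2L, zero_floor = 1,
                            noninformative_as_zero = FALSE) {
  if (fold <= 1) ls_stop("fold must be > 1", "loopscore_parameter_error")
  n <- nrow(cm$values)
  v <- cm$values
  inf <- cm$informative
  idx <- which(inf & upper.tri(inf, diag = TRUE), arr.ind = TRUE)
  med <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    ri <- max(1L, i - half_window):min(n, i + half_window)
    rj <- max(1L, j - half_window):min(n, j + half_window)
    w <- v[ri, rj]
    if (noninformative_as_zero) {
      w[is.na(w)] <- 0
    } else {
      w <- w[!is.na(w)]
    }
    med[k] <- stats::median(w)
  }
  eff <- ifelse(med <= 0, zero_floor, med)
  drop <- v[idx] >= fold * eff
  removed <- data.frame(i = idx[drop, 1L], j = idx[drop, 2L],
                        count = v[idx[drop, , drop = FALSE]],
                        window_median = med[drop])
  inf2 <- inf
  if (any(drop)) {
    di <- idx[drop, , drop = FALSE]
    inf2[di] <- FALSE
    inf2[di[, c(2L, 1L), drop = FALSE]] <- FALSE
  }
  v2 <- v
  v2[!inf2] <- NA_real_
  list(matrix = contact_matrix(v2, inf2, cm$axis, cm$level), removed = removed)
}

#' Convert primer-pair counts to fragment-fragment counts
#'
#' Each fragment pair's value is the arithmetic mean of the surviving
#' informative primer-pair counts mapping to it (one or two values in
#' designs carrying both a forward- and a reverse-sense primer on a
#' fragment); fragment pairs with no surviving primer pair are
#' non-informative.
#'
#' @param cm primer-level [contact_matrix()] after outlier removal.
#' @param design the `primer_design`.
#' @return fragment-level [contact_matrix()].
#' @export
primer_to_fragment <- function(cm, design) {
  frag <- design$primers$fragment_index
  nf <- nrow(design$fragments)
  idx <- cm_upper_pairs(cm)
  s <- matrix(0, nf, nf)
  cnt <- matrix(0L, nf, nf)
  for (k in seq_len(nrow(idx))) {
    f <- frag[idx[k, 1L]]; g <- frag[idx[k, 2L]]
    a <- min(f, g); b <- max(f, g)
    s[a, b] <- s[a, b] + cm$values[idx[k, 1L], idx[k, 2L]]
    cnt[a, b] <- cnt[a, b] + 1L
  }
  inf <- cnt > 0L
  v <- ifelse(inf, s / pmax(cnt, 1L), NA_real_)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  inf <- inf | t(inf)
  contact_matrix(v, inf, design$fragments, "fragment")
}

# Bin table tiling the region spanned by an axis.
make_bins <- function(axis, bin_size) {
  region_start <- min(axis$start)
  region_end <- max(axis$end)
  starts <- seq(region_start, region_end - 1, by = bin_size)
  ends <- pmin(starts + bin_size, region_end)
  genomic_intervals(axis$chrom[1L], starts, ends)
}

#' Bin fragment-level counts to an adjacent-bin grid
#'
#' The relative interaction frequency of bins (i, j) is the sum, over
#' informative fragment pairs {f, g}, of the fragment-pair value whenever f
#' overlaps (at least partially) the `window`-wide interval centered on bin
#' i and g overlaps the window of bin j, or vice versa (each unordered
#' fragment pair contributes once per bin pair). A bin pair is informative
#' iff at least one fragment pair contributes. Windows are half-open and
#' truncated at the region edges.
#'
#' @param cm fragment-level [contact_matrix()].
#' @param bin_size bin width in bp (default 4000).
#' @param window window width in bp (default 12000; must be >= `bin_size`).
#' @return bin-level [contact_matrix()].
#' @export
bin_to_grid <- function(cm, bin_size = 4000, window = 12000) {
  if (window < bin_size) {
    ls_stop("window must be >= bin_size", "loopscore_parameter_error")
  }
  bins <- make_bins(cm$axis, bin_size)
  nb <- nrow(bins)
  centers <- (bins$start + bins$end) / 2
  frag <- cm$axis
  # fragment f overlaps the half-open window [c - w/2, c + w/2) of bin b
  fb_grid <- expand.grid(f = seq_len(nrow(frag)), b = seq_len(nb))
  keep <- frag$start[fb_grid$f] < centers[fb_grid$b] + window / 2 &
    frag$end[fb_grid$f] > centers[fb_grid$b] - window / 2
  fb_grid <- fb_grid[keep, , drop = FALSE]
  bins_of <- split(fb_grid$b, factor(fb_grid$f, levels = seq_len(nrow(frag))))
  idx <- cm_upper_pairs(cm)
  v <- matrix(0, nb, nb)
  inf <- matrix(FALSE, nb, nb)
  if (nrow(idx) > 0L && nrow(fb_grid) > 0L) {
    # cross-expand window-bin sets of both fragments, in both orderings,
    # then drop duplicate (pair, bin_i, bin_j) combinations so each
    # unordered fragment pair contributes once per bin pair
    expand_pairs <- function(fs, gs) {
      bf <- bins_of[fs]
      bg <- bins_of[gs]
      lf <- lengths(bf)
      lg <- lengths(bg)
      pid <- rep.int(seq_along(fs), lf * lg)
      b <- unlist(mapply(function(x, n) rep(x, each = n), bf, lg,
                         SIMPLIFY = FALSE), use.names = FALSE)
      b2 <- unlist(mapply(function(x, n) rep.int(x, n), bg, lf,
                          SIMPLIFY = FALSE), use.names = FALSE)
      data.table::data.table(pid = pid, b = b, b2 = b2)
    }
    both <- unique(rbind(expand_pairs(idx[, 1L], idx[, 2L]),
                         expand_pairs(idx[, 2L], idx[, 1L])))
    both[, "val" := cm$values[idx][both$pid]]
    agg <- both[, list(value = sum(val)), by = c("b", "b2")]
    v[cbind(agg$b, agg$b2)] <- agg$value
    inf[cbind(agg$b, agg$b2)] <- TRUE
  }
  v[!inf] <- NA_real_
  contact_matrix(v, inf, bins, "bin")
}
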