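# Independent brute-force oracles used to verify the implementation. These
# deliberately share no code with the package: explicit loops and direct
# enumeration only.

# --- fixtures -------------------------------------------------------------

# Random symmetric all-informative contact matrix (off-diagonal informative).
random_contact_matrix <- function(n, lambda = 20, level = "primer",
                                  informative_frac = 1, continuous = FALSE) {
  v <- matrix(0, n, n)
  up <- which(upper.tri(v), arr.ind = TRUE)
  v[up] <- if (continuous) stats::rlnorm(nrow(up), log(lambda), 0.5)
           else stats::rpois(nrow(up), lambda)
  v <- v + t(v)
  inf <- matrix(TRUE, n, n)
  diag(inf) <- FALSE
  if (informative_frac < 1) {
    drop <- up[stats::runif(nrow(up)) > informative_frac, , drop = FALSE]
    inf[drop] <- FALSE
    inf[drop[, c(2, 1), drop = FALSE]] <- FALSE
  }
  v[!inf] <- NA_real_
  axis <- data.frame(chrom = "chrT", start = (seq_len(n) - 1) * 1000,
                     end = seq_len(n) * 1000)
  contact_matrix(v, inf, axis, level)
}

# Small hand-buildable primer design: fragments tiling [0, n*len) with the
# four-state orientation cycle.
toy_design <- function(n = 8, len = 2000) {
  frags <- genomic_intervals("chrT", (seq_len(n) - 1) * len, seq_len(n) * len)
  design_primers(frags)
}

# --- outlier filter oracle ------------------------------------------------

# Direct enumeration of the 5x5 (or (2h+1)^2) window median for every
# informative cell; returns logical matrix of removals.
oracle_outlier_removals <- function(cm, fold = 8, half_window = 2,
                                    zero_floor = 1) {
  v <- cm$values
  n <- nrow(v)
  rm_mat <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (!cm$informative[i, j]) next
    vals <- c()
    for (ii in (i - half_window):(i + half_window)) {
      for (jj in (j - half_window):(j + half_window)) {
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && cm$informative[ii, jj]) {
          vals <- c(vals, v[ii, jj])
        }
      }
    }
    med <- stats::median(vals)
    if (med <= 0) med <- zero_floor
    if (v[i, j] >= fold * med) rm_mat[i, j] <- TRUE
  }
  rm_mat | t(rm_mat)
}

# --- binning oracle -------------------------------------------------------

# O(F^2 * B^2) double loop over bin pairs and fragment pairs.
oracle_bin_to_grid <- function(cm, bin_size, window) {
  frag <- cm$axis
  region_start <- min(frag$start)
  region_end <- max(frag$end)
  starts <- seq(region_start, region_end - 1, by = bin_size)
  ends <- pmin(starts + bin_size, region_end)
  nb <- length(starts)
  centers <- (starts + ends) / 2
  nf <- nrow(frag)
  in_window <- function(f, b) {
    frag$start[f] < centers[b] + window / 2 && frag$end[f] > centers[b] - window / 2
  }
  v <- matrix(0, nb, nb)
  inf <- matrix(FALSE, nb, nb)
  for (bi in 1:nb) for (bj in 1:nb) {
    for (f in 1:(nf - 1)) for (g in (f + 1):nf) {
      if (!cm$informative[f, g]) next
      if ((in_window(f, bi) && in_window(g, bj)) ||
          (in_window(g, bi) && in_window(f, bj))) {
        v[bi, bj] <- v[bi, bj] + cm$values[f, g]
        inf[bi, bj] <- TRUE
      }
    }
  }
  v[!inf] <- NA_real_
  list(values = v, informative = inf)
}

# --- ICE oracle -----------------------------------------------------------

# Independent iterative scaling with square-root damped updates; converges to
# the same balanced fixed point. Biases normalized to geometric mean 1 as in
# the implementation contract, making the balanced matrix unique.
oracle_ice <- function(cm, min_separation = 1, iters = 3000) {
  v <- cm$values
  n <- nrow(v)
  mask <- cm$informative
  for (i in 1:n) for (j in 1:n) if (abs(i - j) < min_separation) mask[i, j] <- FALSE
  raw <- ifelse(mask, v, 0)
  raw[is.na(raw)] <- 0
  included <- rowSums(raw) > 0
  mask[!included, ] <- FALSE
  mask[, !included] <- FALSE
  raw[!mask] <- 0
  b <- rep(1, n)
  for (it in 1:iters) {
    V <- raw / outer(b, b)
    r <- rowSums(V)
    m <- mean(r[included])
    f <- sqrt(r / m)
    f[!included | f == 0] <- 1
    b <- b * f
  }
  b[included] <- b[included] / exp(mean(log(b[included])))
  b[!included] <- NA
  V <- cm$values / outer(b, b)
  V[!mask] <- NA_real_
  list(values = V, biases = b, included = included)
}

# --- donut oracle ---------------------------------------------------------

# Per-pixel explicit ring enumeration with a per-diagonal reference.
oracle_donut <- function(cm, w = 5, p_excl = 2, min_ring = 10,
                         decay_stat = "median") {
  v <- cm$values
  n <- nrow(v)
  fstat <- if (decay_stat == "median") stats::median else mean
  ref <- rep(NA_real_, 2 * n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in 1:n) {
      j <- i + d
      if (j <= n && cm$informative[i, j]) vals <- c(vals, v[i, j])
    }
    if (length(vals) > 0) ref[d + 1] <- fstat(vals)
  }
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (!cm$informative[i, j]) next
    so <- 0; se <- 0; cnt <- 0
    for (di in -w:w) for (dj in -w:w) {
      ch <- max(abs(di), abs(dj))
      if (ch <= p_excl || ch > w) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n || jj < 1 || jj > n) next
      if (!cm$informative[ii, jj]) next
      so <- so + v[ii, jj]
      se <- se + ref[abs(ii - jj) + 1]
      cnt <- cnt + 1
    }
    if (cnt >= min_ring && se > 0) {
      out[i, j] <- so / se * ref[abs(i - j) + 1]
    }
  }
  out
}

# --- statistics oracles ---------------------------------------------------

# Method-of-moments logistic estimator (independent of the ML route).
oracle_logistic_moments <- function(x) {
  c(location = mean(x), scale = stats::sd(x) * sqrt(3) / pi)
}

# Full hypergeometric enumeration of the two-tailed Fisher p for a 2x2 table,
# using exact choose() arithmetic.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  denom <- choose(N, c1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / denom
  p_obs <- prob(a)
  xs <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(xs, function(x) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) px else 0
  }, numeric(1)))
}

# KS D by explicit ECDF evaluation at every pooled point.
oracle_ks_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  d <- 0
  for (x in xs) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# Monte-Carlo permutation estimate of P(D_perm >= D_obs).
perm_ks_p <- function(a, b, B = 10000) {
  pool <- c(a, b)
  na <- length(a)
  n <- length(pool)
  d_obs <- oracle_ks_D(a, b)
  ord <- order(pool)
  cnt <- 0L
  for (k in seq_len(B)) {
    lab <- logical(n)
    lab[sample.int(n, na)] <- TRUE
    lo <- lab[ord]
    D <- max(abs(cumsum(lo) / na - cumsum(!lo) / (n - na)))
    if (D >= d_obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / B
}
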