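# Internal helpers: reproducible sub-stream seeding and masked matrix sums.

#' Derive a deterministic sub-stream seed
#'
#' Maps a master seed and a character key to a 32-bit seed, so independent
#' parts of a simulation (fragment layout, biases, counts per replicate, ...)
#' draw from reproducible, separately re-runnable streams.
#'
#' @param seed integer master seed.
#' @param key character label of the sub-stream.
#' @return a positive integer < 2^31.
#' @keywords internal
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1
  s <- abs(as.numeric(seed)) %% m
  for (c in utf8ToInt(key)) {
    # multiplier small enough that s * 69069 + c stays exact in doubles
    s <- (s * 69069 + c) %% m
  }
  as.integer(s %% (m - 1L) + 1L)
}

# Evaluate `code` with the RNG seeded from (seed, key), restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, key, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  force(code)
}

# Sum of M over a set of index offsets: out[i, j] = sum_k M[i + di_k, j + dj_k],
# out-of-bounds cells contributing 0. Used for donut ring sums; O(n^2 * |offsets|)
# with vectorized shifts.
offset_sum <- function(M, offsets) {
  n <- nrow(M)
  m <- ncol(M)
  out <- matrix(0, n, m)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets[k, 1L]
    dj <- offsets[k, 2L]
    src_i <- max(1L, 1L + di):min(n, n + di)
    src_j <- max(1L, 1L + dj):min(m, m + dj)
    if (length(src_i) == 0L || length(src_j) == 0L) next
    out[src_i - di, src_j - dj] <- out[src_i - di, src_j - dj] + M[src_i, src_j]
  }
  out
}

# Stop with a consistent error class so tests can target failures precisely.
ls_stop <- function(msg, class) {
  stop(structure(class = c(class, "loopscore_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
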