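decay_matrix <- function(n, scale = 1000, alpha = 1) {
  simulate_binned_matrix(n, scale = scale, alpha = alpha, dispersion = 0)
}

test_that("donut expected equals the constant on a constant matrix interior", {
  n <- 30
  v <- matrix(7, n, n)
  inf <- matrix(TRUE, n, n); diag(inf) <- FALSE; v[!inf] <- NA
  cm <- contact_matrix(v, inf, data.frame(chrom = "c", start = 0:(n - 1) * 10,
                                          end = 1:n * 10), "bin")
  ex <- donut_expected(cm)
  interior <- ex$values[10:20, 10:20]
  expect_equal(interior[!is.na(interior)], rep(7, sum(!is.na(interior))))
})

test_that("pure distance-decay matrices give ratios within 1% of unity", {
  cm <- decay_matrix(40)
  ex <- donut_expected(cm)
  ratio <- background_normalize(cm, ex)
  inner <- ratio[8:33, 8:33]
  inner <- inner[!is.na(inner)]
  expect_true(all(inner > 0.99 & inner < 1.01))
})

test_that("a spiked pixel keeps its own donut clean and recovers the spike fold", {
  n <- 30
  v <- matrix(6, n, n)
  inf <- matrix(TRUE, n, n); diag(inf) <- FALSE
  v[12, 20] <- v[20, 12] <- 30 # 5x the background
  v[!inf] <- NA
  cm <- contact_matrix(v, inf, data.frame(chrom = "c", start = 0:(n - 1) * 10,
                                          end = 1:n * 10), "bin")
  ex <- donut_expected(cm, decay_stat = "median")
  expect_equal(ex$values[12, 20], 6, tolerance = 1e-9) # spike inside excluded center
  ratio <- background_normalize(cm, ex)
  expect_equal(ratio[12, 20], 5, tolerance = 1e-9)
})

test_that("donut expected matches the ring-enumeration oracle elementwise", {
  set.seed(41)
  for (k in 1:3) {
    cm <- random_contact_matrix(30, lambda = 25, level = "bin",
                                informative_frac = c(1, 0.9, 0.8)[k])
    for (stat in c("median", "mean")) {
      ex <- donut_expected(cm, w = 5, p_excl = 2, min_ring = 10, decay_stat = stat)
      oc <- oracle_donut(cm, w = 5, p_excl = 2, min_ring = 10, decay_stat = stat)
      expect_identical(is.na(ex$values), is.na(oc))
      expect_lt(max(abs(ex$values - oc), na.rm = TRUE), 1e-9)
    }
  }
  expect_error(donut_expected(decay_matrix(20), w = 2, p_excl = 2),
               class = "loopscore_parameter_error")
})

test_that("background normalization divides observed by expected and propagates NA", {
  cm <- decay_matrix(20)
  ex <- donut_expected(cm)
  ratio <- background_normalize(cm, ex)
  i <- which(!is.na(ratio), arr.ind = TRUE)[1, ]
  expect_equal(ratio[i[1], i[2]], cm$values[i[1], i[2]] / ex$values[i[1], i[2]])
  expect_true(all(is.na(ratio[is.na(ex$values)])))
})

test_that("logistic fit recovers parameters from simulated draws and flags bad input", {
  set.seed(42)
  x <- stats::rlogis(10000, location = 0, scale = 1)
  fit <- fit_logistic(x)
  expect_lt(abs(fit["location"]), 0.05)
  expect_lt(abs(fit["scale"] - 1), 0.05)
  # ML agrees with the method-of-moments oracle to first order
  mom <- oracle_logistic_moments(x)
  expect_lt(abs(fit["location"] - mom["location"]), 0.05)
  expect_lt(abs(fit["scale"] - mom["scale"]), 0.1)
  # symmetric sample: location near the center of symmetry
  y <- 1 + c(x[1:5000], -x[1:5000])
  expect_lt(abs(fit_logistic(y)["location"] - 1), 0.05)
  # an extreme outlier inflates the fitted scale
  z <- stats::rlogis(500, 1, 0.2)
  expect_gt(fit_logistic(c(z, 50))["scale"], fit_logistic(z)["scale"])
  expect_error(fit_logistic(rep(1, 100)), class = "loopscore_degenerate_fit_error")
  expect_error(fit_logistic(stats::rlogis(10)), class = "loopscore_insufficient_data_error")
})

test_that("interaction scores are exact at reference p-values and monotone", {
  sm <- pvalues_and_scores(c(-1e9, 0, log(3)), location = 0, scale = 1)
  # x -> -inf gives p -> 1, score 0; x = location gives p = 0.5, score 10
  expect_equal(sm$p_value[1], 1)
  expect_equal(sm$score[1], 0)
  expect_equal(sm$p_value[2], 0.5)
  expect_equal(sm$score[2], 10)
  expect_equal(sm$p_value[3], 0.25)
  expect_equal(sm$score[3], 20)
  # monotone decreasing in p, floored at p_floor
  p <- seq(1e-13, 1, length.out = 50)
  x <- stats::qlogis(p, lower.tail = FALSE)
  sm2 <- pvalues_and_scores(x, 0, 1, p_floor = 1e-12)
  expect_true(all(diff(sm2$score[order(sm2$p_value)]) <= 0))
  expect_lte(max(sm2$score), -10 * log2(1e-12))
})

test_that("loop-pixel quantification averages the anchor rectangle", {
  n <- 12
  v <- matrix(NA_real_, n, n)
  inf <- matrix(FALSE, n, n)
  v[3, 8] <- v[8, 3] <- 7; inf[3, 8] <- inf[8, 3] <- TRUE
  v[3, 9] <- v[9, 3] <- 1; inf[3, 9] <- inf[9, 3] <- TRUE
  v[4, 8] <- v[8, 4] <- 2; inf[4, 8] <- inf[8, 4] <- TRUE
  v[4, 9] <- v[9, 4] <- 3; inf[4, 9] <- inf[9, 4] <- TRUE
  axis <- data.frame(chrom = "c", start = 0:(n - 1) * 4000, end = 1:n * 4000)
  cm <- contact_matrix(v, inf, axis, "bin")
  a1 <- genomic_intervals("c", 8000, 12000)    # bin 3 only
  a2 <- genomic_intervals("c", 28000, 32000)   # bin 8 only
  expect_equal(quantify_loop_pixels(cm, a1, a2)$mean, 7)
  wide1 <- genomic_intervals("c", 8000, 16000)  # bins 3:4
  wide2 <- genomic_intervals("c", 28000, 36000) # bins 8:9
  q <- quantify_loop_pixels(cm, wide1, wide2)
  expect_equal(q$mean, mean(c(7, 1, 2, 3)))
  expect_equal(q$n_pixels, 4)
  # fully non-informative rectangle -> undefined
  empty <- quantify_loop_pixels(cm, genomic_intervals("c", 0, 4000),
                                genomic_intervals("c", 40000, 44000))
  expect_true(is.na(empty$mean))
  expect_error(quantify_loop_pixels(cm, genomic_intervals("chrZ", 0, 10), a2),
               class = "loopscore_validation_error")
})

test_that("distance-corrected loop strength is the mean pixel-wise obs/exp", {
  cm <- decay_matrix(30)
  ex <- donut_expected(cm)
  a1 <- cm$axis[10, , drop = FALSE]
  a2 <- cm$axis[22, , drop = FALSE]
  expect_equal(distance_corrected_loop_strength(cm, ex, a1, a2)$ratio, 1,
               tolerance = 1e-6)
  # observed = 3 x expected everywhere on the rectangle -> 3
  v3 <- cm$values * 3
  cm3 <- contact_matrix(v3, cm$informative, cm$axis, "bin")
  ex3 <- ex
  expect_equal(distance_corrected_loop_strength(cm3, ex3, a1, a2)$ratio, 3,
               tolerance = 1e-6)
})

test_that("planted loop pixels outscore distance-matched background", {
  loops <- data.frame(i = c(10, 25), j = c(40, 70), fold = 5)
  detected <- 0
  for (sd in 1:5) {
    cm <- simulate_binned_matrix(90, scale = 2000, dispersion = 0.05,
                                 loops = loops, seed = sd)
    sm <- score_matrix(cm, donut_expected(cm))
    n <- nrow(cm$values)
    sep <- abs(outer(1:n, 1:n, "-"))
    ok <- TRUE
    for (k in 1:2) {
      sc <- sm$score[loops$i[k], loops$j[k]]
      bgd <- sm$score[sep == abs(loops$i[k] - loops$j[k]) &
                        upper.tri(sm$score) & !is.na(sm$score)]
      bgd <- bgd[bgd != sc]
      ok <- ok && sc > stats::quantile(bgd, 0.99)
    }
    detected <- detected + ok
  }
  expect_gte(detected, 4)
})
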