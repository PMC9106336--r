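test_that("simulated fragments tile the region exactly and deterministically", {
  cfg <- sim_config(region_length = 40000, planted_loops = NULL, seed = 1)
  fr <- simulate_fragments(cfg)
  expect_equal(fr$start[1], 0)
  expect_equal(fr$end[nrow(fr)], 40000)
  expect_equal(fr$start[-1], fr$end[-nrow(fr)]) # contiguous, no gaps
  fr2 <- simulate_fragments(cfg)
  expect_identical(fr, fr2)
  expect_error(simulate_fragments(sim_config(region_length = 40000,
                                             planted_loops = NULL,
                                             mean_fragment_length = 450)),
               class = "loopscore_config_error")
})

test_that("realized fragment lengths match the configured mean on a long region", {
  cfg <- sim_config(region_length = 1e6, mean_fragment_length = 2000,
                    planted_loops = NULL, seed = 2)
  fr <- simulate_fragments(cfg)
  expect_lt(abs(mean(fr$end - fr$start) - 2000) / 2000, 0.10)
})

test_that("primer design follows the four-state double-alternating cycle", {
  des <- toy_design(n = 8)
  expect_equal(des$primers$orientation[1:4], c("FOR", "LREV", "REV", "LFOR"))
  expect_equal(des$primers$orientation[5:8], c("FOR", "LREV", "REV", "LFOR"))
  # adjacent FOR/LREV are opposite sense, hence queryable
  expect_true(queryable_pair("FOR", "LREV"))
  expect_true(queryable_pair("LFOR", "REV"))
  expect_false(queryable_pair("FOR", "LFOR")) # same sense
  expect_false(queryable_pair("REV", "LREV"))
  # primer intervals sit inside their fragments
  expect_true(all(des$primers$start >= des$fragments$start &
                    des$primers$end <= des$fragments$end))
})

test_that("simulated counts are symmetric, integer, deterministic, with missing non-queryable pairs", {
  cfg <- sim_config(region_length = 100000, library_size = 2e5,
                    planted_loops = NULL, seed = 5)
  des <- design_primers(simulate_fragments(cfg))
  mats <- simulate_counts(cfg, des)
  expect_equal(length(mats), nrow(cfg$conditions) * cfg$n_replicates)
  m <- mats[[1]]
  expect_identical(m$values, t(m$values))
  v <- m$values[m$informative]
  expect_true(all(v >= 0 & v == round(v)))
  # non-queryable pairs carry no value
  expect_true(all(is.na(m$values[!m$informative])))
  fwd <- is_forward_sense(des$primers$orientation)
  expect_identical(m$informative, {
    q <- outer(fwd, fwd, FUN = xor); diag(q) <- FALSE; q
  })
  mats2 <- simulate_counts(cfg, des)
  expect_identical(mats[[1]]$values, mats2[[1]]$values) # bitwise determinism
})

test_that("mean counts follow the configured power-law distance decay", {
  cfg <- sim_config(region_length = 400000, library_size = 5e6, bias_sd = 0,
                    dispersion = 0, planted_loops = NULL, n_spikes = 0,
                    n_replicates = 1, decay_exponent = 1,
                    conditions = data.frame(name = "TTX", stimulated = FALSE,
                                            depleted = FALSE),
                    seed = 3)
  des <- design_primers(simulate_fragments(cfg))
  m <- simulate_counts(cfg, des)[[1]]
  mids <- midpoint(des$fragments)[des$primers$fragment_index]
  d <- abs(outer(mids, mids, "-"))
  up <- which(m$informative & upper.tri(d), arr.ind = TRUE)
  dist <- pmax(d[up], cfg$bin_size)
  cnt <- m$values[up]
  # regression of log mean count on log distance over distance bins
  br <- cut(log(dist), breaks = 12)
  mu <- tapply(cnt, br, mean)
  ld <- tapply(log(dist), br, mean)
  keep <- !is.na(mu) & mu > 0
  slope <- stats::coef(stats::lm(log(mu[keep]) ~ ld[keep]))[2]
  expect_lt(abs(slope - (-1)) / 1, 0.05)
})

test_that("planted loops enrich counts by their fold at distance-matched pairs", {
  loops <- data.frame(name = "L", bin_i = 10, bin_j = 35, fold = 5,
                      inducible = FALSE, ctcf = FALSE)
  cfg <- sim_config(region_length = 200000, library_size = 1e6, bias_sd = 0,
                    dispersion = 0.05, planted_loops = loops, n_spikes = 0,
                    n_replicates = 50,
                    conditions = data.frame(name = "TTX", stimulated = FALSE,
                                            depleted = FALSE),
                    seed = 4)
  des <- design_primers(simulate_fragments(cfg))
  mats <- simulate_counts(cfg, des)
  fr <- des$fragments[des$primers$fragment_index, ]
  half_w <- cfg$loop_halo_bins * cfg$bin_size + cfg$bin_size / 2
  memb <- function(b) {
    c0 <- (b - 0.5) * cfg$bin_size
    fr$start < c0 + half_w & fr$end > c0 - half_w
  }
  in_loop <- outer(memb(10), memb(35)) | outer(memb(35), memb(10))
  mids <- midpoint(des$fragments)[des$primers$fragment_index]
  d <- pmax(abs(outer(mids, mids, "-")), cfg$bin_size)
  target_d <- range(d[in_loop & !is.na(mats[[1]]$values)])
  matched <- d >= target_d[1] & d <= target_d[2] & !in_loop
  tot <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m$values), 0, m$values)))
  ratio <- mean(tot[in_loop & mats[[1]]$informative]) /
    mean(tot[matched & mats[[1]]$informative])
  expect_lt(abs(ratio - 5) / 5, 0.10)
})

test_that("inducible and cohesin-dependent loop enrichment follows the condition design", {
  loops <- data.frame(name = c("ind", "ctcf"), bin_i = c(8, 12), bin_j = c(30, 40),
                      fold = c(4, 4), inducible = c(TRUE, FALSE),
                      ctcf = c(FALSE, TRUE))
  conds <- default_conditions()
  for (k in seq_len(nrow(conds))) {
    cond <- conds[k, ]
    f_ind <- loopscore:::loop_fold_in_condition(loops[1, ], cond)
    f_ctcf <- loopscore:::loop_fold_in_condition(loops[2, ], cond)
    expect_equal(f_ind, if (cond$stimulated) 4 else 1)
    expect_equal(f_ctcf, if (cond$depleted) 1 else 4)
  }
})

test_that("PCR spikes are planted on queryable pairs and multiply counts", {
  sp <- data.frame(i = 1, j = 2, fold = 40) # FOR_1 x LREV_2: queryable
  cfg <- sim_config(region_length = 100000, spike_pairs = sp, planted_loops = NULL,
                    n_replicates = 1,
                    conditions = data.frame(name = "TTX", stimulated = FALSE,
                                            depleted = FALSE),
                    seed = 6)
  des <- design_primers(simulate_fragments(cfg))
  m <- simulate_counts(cfg, des)[[1]]
  neighbors <- m$values[1, 3:8]
  expect_gt(m$values[1, 2], 8 * stats::median(neighbors, na.rm = TRUE))
})

test_that("gene-loop fixture realizes planted span separation and class structure", {
  cfg <- gene_loop_config(seed = 9)
  fix <- simulate_gene_loop_fixture(cfg)
  expect_equal(nrow(fix$genes), 18 + 22 + 43 + 60)
  expect_equal(length(fix$ieg), 18)
  expect_equal(length(fix$lrg), 65)
  gl <- gene_loop_table(fix$genes, fix$loops, fix$peaks, fix$enhancers)
  longest <- loop_span_per_gene(fix$genes, gl, filter = "all", stat = "longest")
  cls <- fix$genes$class_label[match(longest$gene_id, fix$genes$gene_id)]
  med_down <- stats::median(longest$span[cls == "down_lrg"])
  med_nond <- stats::median(longest$span[cls == "nondereg_lrg"])
  expect_gt(med_down, med_nond) # planted 500 kb vs 100 kb ordering
  # generator and classifier round-trip: planted DE statuses map back to the
  # planted classes
  asg <- assign_expression_class(fix$genes, fix$ieg, fix$lrg)
  expect_equal(asg$expression_class[fix$genes$class_label == "down_lrg"],
               rep("downregulated_LRG", 22))
  expect_equal(asg$expression_class[fix$genes$class_label == "nondereg_lrg"],
               rep("non_deregulated_LRG", 43))
  expect_equal(asg$expression_class[fix$genes$class_label == "constitutive"],
               rep("constitutive", 60))
  expect_equal(asg$expression_class[fix$genes$class_label == "IEG"],
               rep("IEG", 18))
  # determinism
  fix2 <- simulate_gene_loop_fixture(cfg)
  expect_identical(fix$loops, fix2$loops)
  expect_identical(fix$genes, fix2$genes)
})

test_that("empty fixture config yields empty outputs", {
  fix <- simulate_gene_loop_fixture(gene_loop_config(n_ieg = 0, n_down_lrg = 0,
                                                     n_nondereg_lrg = 0,
                                                     n_constitutive = 0))
  expect_equal(nrow(fix$genes), 0)
  expect_equal(nrow(fix$loops), 0)
  expect_equal(nrow(fix$peaks), 0)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(region_length = 30000), class = "loopscore_config_error")
  expect_error(sim_config(planted_loops = data.frame(
    name = "x", bin_i = 500, bin_j = 600, fold = 2,
    inducible = FALSE, ctcf = FALSE)), class = "loopscore_config_error")
  expect_error(sim_config(planted_loops = data.frame(
    name = "x", bin_i = 5, bin_j = 20, fold = 0.5,
    inducible = FALSE, ctcf = FALSE)), class = "loopscore_config_error")
  expect_error(sim_config(n_replicates = 0), class = "loopscore_config_error")
})
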