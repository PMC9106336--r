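mk_loop <- function(s1, e1, s2, e2, chrom = "chr1") {
  data.frame(chrom = chrom, start1 = s1, end1 = e1, start2 = s2, end2 = e2,
             name = NA_character_)
}

test_that("CTCF loop classification requires a peak inside an anchor", {
  loop <- mk_loop(1000, 2000, 50000, 51000)
  peak_in <- data.frame(chrom = "chr1", start = 1500, end = 1600, label = "CTCF",
                        inducible = NA)
  peak_between <- data.frame(chrom = "chr1", start = 10000, end = 10100,
                             label = "CTCF", inducible = NA)
  peak_edge <- data.frame(chrom = "chr1", start = 50999, end = 51200,
                          label = "CTCF", inducible = NA) # 1 bp overlap
  expect_true(classify_ctcf_loop(loop, peak_in))
  expect_false(classify_ctcf_loop(loop, peak_between))
  expect_true(classify_ctcf_loop(loop, peak_edge))
})

test_that("enhancer-promoter classification follows TSS and enhancer placement", {
  loop <- mk_loop(1000, 2000, 50000, 51000)
  enh_ind <- data.frame(chrom = "chr1", start = 50400, end = 50600,
                        label = "enhancer", inducible = TRUE)
  enh_con <- data.frame(chrom = "chr1", start = 50400, end = 50600,
                        label = "enhancer", inducible = FALSE)
  expect_true(classify_ep_loop(loop, tss = 1500, chrom = "chr1", enh_ind,
                               require_inducible = TRUE))
  expect_false(classify_ep_loop(loop, tss = 1500, chrom = "chr1", enh_con,
                                require_inducible = TRUE))
  expect_true(classify_ep_loop(loop, tss = 1500, chrom = "chr1", enh_con,
                               require_inducible = FALSE))
  expect_false(classify_ep_loop(loop, tss = 30000, chrom = "chr1", enh_ind,
                                require_inducible = TRUE)) # TSS in neither anchor
  # symmetric: TSS in distal anchor, enhancer in proximal one
  enh_prox <- data.frame(chrom = "chr1", start = 1200, end = 1300,
                         label = "enhancer", inducible = TRUE)
  expect_true(classify_ep_loop(loop, tss = 50500, chrom = "chr1", enh_prox,
                               require_inducible = TRUE))
})

test_that("loop span is the anchor-midpoint distance with floor semantics", {
  expect_equal(loop_span(mk_loop(100, 200, 500, 700)), 450)
  expect_equal(loop_span(mk_loop(0, 10000, 1000000, 1010000)), 1000000)
  # symmetric widening about the midpoints leaves the span unchanged
  base <- mk_loop(1000, 2000, 9000, 10000)
  widened <- mk_loop(500, 2500, 8500, 10500)
  expect_equal(loop_span(base), loop_span(widened))
  trans <- mk_loop(100, 200, 500, 700)
  trans$chrom2 <- "chr2"
  expect_error(loop_span(trans), class = "loopscore_validation_error")
})

test_that("per-gene span summaries apply the no-loop inclusion rules", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(1500, 900000))
  loops <- rbind(mk_loop(1000, 2000, 50000, 52000),   # gA, span 49.5 kb
                 mk_loop(1000, 2000, 400000, 402000)) # gA, span 399.5 kb
  peaks <- data.frame(chrom = "chr1", start = 1400, end = 1600, label = "CTCF",
                      inducible = NA)
  enh <- data.frame(chrom = "chr1", start = 50500, end = 51000,
                    label = "enhancer", inducible = TRUE)
  gl <- gene_loop_table(genes, loops, peaks, enh)
  longest <- loop_span_per_gene(genes, gl, filter = "all", stat = "longest")
  expect_equal(longest$span[longest$gene_id == "gA"], 399500)
  # gB has no loops: included as 0 for all/ctcf
  expect_equal(longest$span[longest$gene_id == "gB"], 0)
  expect_false(longest$had_loop[longest$gene_id == "gB"])
  avg <- loop_span_per_gene(genes, gl, filter = "all", stat = "mean")
  expect_equal(avg$span[avg$gene_id == "gA"], mean(c(49500, 399500)))
  expect_equal(avg$span[avg$gene_id == "gB"], 0)
  # enhancer-promoter filter: loop 1 qualifies; no-loop genes are excluded
  ep <- loop_span_per_gene(genes, gl, filter = "enhancer_promoter", stat = "longest")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$span, 49500)
  ctcf <- loop_span_per_gene(genes, gl, filter = "ctcf", stat = "longest")
  expect_equal(ctcf$span[ctcf$gene_id == "gA"], 399500)
})

test_that("expression class assignment applies the dysregulation rules and partitions", {
  mk_gene <- function(id, p1, p2, f1 = -1, f2 = -1, pi1 = 0.5, pi2 = 0.5,
                      fi1 = 0, fi2 = 0, expr = TRUE) {
    data.frame(gene_id = id, chrom = "chr1", tss = 1000,
               log2fc_nex_ttx = f1, padj_nex_ttx = p1, expressed_nex_ttx = expr,
               log2fc_nex_kcl6 = f2, padj_nex_kcl6 = p2, expressed_nex_kcl6 = expr,
               log2fc_kcl1_vs_ttx = fi1, padj_kcl1_vs_ttx = pi1,
               expressed_kcl1_vs_ttx = expr,
               log2fc_kcl6_vs_ttx = fi2, padj_kcl6_vs_ttx = pi2,
               expressed_kcl6_vs_ttx = expr)
  }
  genes <- rbind(
    mk_gene("lrg_down", 0.01, 0.01),                      # down in both
    mk_gene("lrg_one", 0.01, 0.5),                        # down in TTX only
    mk_gene("lrg_nond", 0.4, 0.6),                        # deregulated in neither
    mk_gene("lrg_sign", 0.01, 0.01, f2 = 0.5),            # significant but discordant
    mk_gene("ieg1", 0.01, 0.9),
    mk_gene("induc", 0.5, 0.5, pi1 = 0.001, fi1 = 2),     # induced by KCl
    mk_gene("const", 0.5, 0.5, pi1 = 0.3, pi2 = 0.4),     # expressed, no induction change
    mk_gene("weak", 0.5, 0.5, pi1 = 0.01, fi1 = 0.5))     # significant but lfc < 1
  asg <- assign_expression_class(genes, ieg_ids = "ieg1",
                                 lrg_ids = c("lrg_down", "lrg_one", "lrg_nond", "lrg_sign"))
  got <- stats::setNames(asg$expression_class, asg$gene_id)
  expect_equal(unname(got["lrg_down"]), "downregulated_LRG")
  expect_equal(unname(got["lrg_one"]), "excluded")
  expect_equal(unname(got["lrg_nond"]), "non_deregulated_LRG")
  expect_equal(unname(got["lrg_sign"]), "excluded")
  expect_equal(unname(got["ieg1"]), "IEG")
  expect_equal(unname(got["induc"]), "inducible")
  expect_equal(unname(got["const"]), "constitutive")
  expect_equal(unname(got["weak"]), "other")
  # partition: every gene classified exactly once, exclusions carry reasons
  expect_false(any(is.na(asg$expression_class)))
  expect_true(all(!is.na(asg$reason[asg$expression_class == "excluded"])))
  # errors: overlapping curated lists, missing contrast columns
  expect_error(assign_expression_class(genes, ieg_ids = "ieg1", lrg_ids = "ieg1"),
               class = "loopscore_validation_error")
  expect_error(assign_expression_class(genes, "ieg1", "lrg_down",
                                       genotype_contrasts = c("nex_ttx", "absent")),
               "absent", class = "loopscore_validation_error")
})

test_that("KS statistic matches explicit ECDF enumeration", {
  ks <- ks_two_sample(c(1, 2, 3), c(1.5, 2.5))
  expect_equal(ks$D, 1 / 3)
  expect_equal(ks_two_sample(1:4, 1:4)$D, 0)
  expect_equal(ks_two_sample(1:4, 1:4)$p, 1)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  set.seed(51)
  for (k in 1:25) {
    a <- stats::rnorm(sample(3:20, 1))
    b <- stats::rnorm(sample(3:20, 1), mean = stats::runif(1, 0, 1))
    expect_equal(ks_two_sample(a, b)$D, oracle_ks_D(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), class = "loopscore_validation_error")
})

test_that("Fisher exact test reproduces enumeration cases and odds-ratio conventions", {
  flat <- fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p, 1)
  strong <- fisher_exact_2x2(matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
  expect_equal(strong$odds_ratio, 81)
  expect_equal(strong$p, 202 / 184756, tolerance = 1e-9)
  sep <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(sep$odds_ratio, Inf)
  expect_equal(sep$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "loopscore_validation_error")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "loopscore_validation_error")
})

test_that("promoter binding enrichment builds the 2x2 table by direct overlap", {
  interest <- data.frame(gene_id = c("i1", "i2", "i3"), chrom = "chr1",
                         tss = c(10000, 50000, 90000))
  background <- data.frame(gene_id = c("b1", "b2"), chrom = "chr1",
                           tss = c(200000, 300000))
  peaks <- data.frame(chrom = "chr1",
                      start = c(9500, 201000), end = c(9700, 201200),
                      label = "CTCF", inducible = NA)
  res <- promoter_binding_enrichment(interest, background, peaks,
                                     promoter_halfwidth = 2000)
  # hand enumeration: i1 bound (peak at 9.5-9.7 kb within 8-12 kb window),
  # b1 bound (201-201.2 kb within 198-202 kb window); i2, i3, b2 unbound
  expect_equal(unname(res$table["bound", ]), c(1, 1))
  expect_equal(unname(res$table["unbound", ]), c(2, 1))
  expect_equal(res$odds_ratio, (1 * 1) / (1 * 2))
  # identical binding rates -> OR 1
  res2 <- promoter_binding_enrichment(
    data.frame(gene_id = c("i1", "i4"), chrom = "chr1", tss = c(10000, 600000)),
    data.frame(gene_id = c("b1", "b2"), chrom = "chr1", tss = c(200000, 300000)),
    peaks, promoter_halfwidth = 2000)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)
  expect_error(promoter_binding_enrichment(interest, interest[0, ], peaks),
               class = "loopscore_validation_error")
  expect_error(promoter_binding_enrichment(interest, interest, peaks),
               class = "loopscore_validation_error")
})
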