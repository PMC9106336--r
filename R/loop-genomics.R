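# Loop classification, span metrics, gene expression classes and the
# span-vs-dysregulation statistics.

loop_anchor <- function(loops, which = 1L) {
  if (which == 1L) {
    data.frame(chrom = loops$chrom, start = loops$start1, end = loops$end1)
  } else {
    data.frame(chrom = loops$chrom, start = loops$start2, end = loops$end2)
  }
}

#' Classify loops as CTCF loops
#'
#' A loop is a CTCF loop iff at least one CTCF peak overlaps (half-open) at
#' least one of its anchors.
#'
#' @param loops loop table (as from [read_bedpe()]).
#' @param ctcf_peaks peak table (as from [read_bed()]).
#' @return logical vector, one per loop.
#' @export
classify_ctcf_loop <- function(loops, ctcf_peaks) {
  if (nrow(loops) == 0L) return(logical(0))
  any_overlap(loop_anchor(loops, 1L), ctcf_peaks) |
    any_overlap(loop_anchor(loops, 2L), ctcf_peaks)
}

#' Classify loops as enhancer-promoter loops for a gene
#'
#' TRUE for a loop iff the gene's TSS falls within one anchor and the other
#' anchor of the same loop overlaps an enhancer. With `require_inducible =
#' TRUE` (used for activity-regulated genes) only activity-induced enhancers
#' qualify; with FALSE (used for constitutive neuronal gene sets) both
#' constitutive and inducible enhancers do.
#'
#' @param loops loop table.
#' @param tss numeric TSS base position (0-based).
#' @param chrom chromosome of the TSS.
#' @param enhancers enhancer table with an `inducible` column.
#' @param require_inducible restrict to activity-induced enhancers.
#' @return logical vector, one per loop.
#' @export
classify_ep_loop <- function(loops, tss, chrom, enhancers, require_inducible = TRUE) {
  if (nrow(loops) == 0L) return(logical(0))
  enh <- enhancers
  if (require_inducible && nrow(enh) > 0L) {
    enh <- enh[!is.na(enh$inducible) & enh$inducible, , drop = FALSE]
  }
  tss_iv <- data.frame(chrom = chrom, start = tss, end = tss + 1)
  in1 <- overlaps(loop_anchor(loops, 1L), tss_iv[rep(1L, nrow(loops)), ])
  in2 <- overlaps(loop_anchor(loops, 2L), tss_iv[rep(1L, nrow(loops)), ])
  e1 <- any_overlap(loop_anchor(loops, 1L), enh)
  e2 <- any_overlap(loop_anchor(loops, 2L), enh)
  (in1 & e2) | (in2 & e1)
}

#' Loop span
#'
#' Genomic distance between the midpoints of the loop's two anchors
#' (midpoints use integer floor). Errors on trans loops.
#'
#' @param loops loop table; a `chrom2` column, if present, must equal `chrom`.
#' @return numeric spans in bp.
#' @export
loop_span <- function(loops) {
  if (!is.null(loops$chrom2) && any(loops$chrom2 != loops$chrom)) {
    ls_stop("loop_span is defined for cis loops only", "loopscore_validation_error")
  }
  abs(midpoint(loop_anchor(loops, 2L)) - midpoint(loop_anchor(loops, 1L)))
}

#' Per-gene loop table
#'
#' For every gene, the loops whose anchors contain the gene's TSS, with span
#' and classification flags.
#'
#' @param genes gene table (`gene_id`, `chrom`, `tss`, ...).
#' @param loops loop table.
#' @param ctcf_peaks CTCF peak table.
#' @param enhancers enhancer table.
#' @param require_inducible passed to [classify_ep_loop()]; may be a single
#'   flag or one per gene.
#' @return data.frame (`gene_id`, `loop_index`, `span`, `is_ctcf`, `is_ep`).
#' @export
gene_loop_table <- function(genes, loops, ctcf_peaks, enhancers,
                            require_inducible = TRUE) {
  empty <- data.frame(gene_id = character(), loop_index = integer(),
                      span = numeric(), is_ctcf = logical(), is_ep = logical())
  if (nrow(loops) == 0L || nrow(genes) == 0L) return(empty)
  is_ctcf <- classify_ctcf_loop(loops, ctcf_peaks)
  spans <- loop_span(loops)
  # anchor-enhancer overlaps are loop properties: compute once for both the
  # inducible-only and any-enhancer variants
  enh_ind <- enhancers[!is.na(enhancers$inducible) & enhancers$inducible, , drop = FALSE]
  e1_all <- any_overlap(loop_anchor(loops, 1L), enhancers)
  e2_all <- any_overlap(loop_anchor(loops, 2L), enhancers)
  e1_ind <- any_overlap(loop_anchor(loops, 1L), enh_ind)
  e2_ind <- any_overlap(loop_anchor(loops, 2L), enh_ind)
  req <- rep_len(require_inducible, nrow(genes))
  rows <- lapply(seq_len(nrow(genes)), function(g) {
    tss <- genes$tss[g]
    same <- loops$chrom == genes$chrom[g]
    hit1 <- same & loops$start1 <= tss & tss < loops$end1
    hit2 <- same & loops$start2 <= tss & tss < loops$end2
    hit <- hit1 | hit2
    if (!any(hit)) return(NULL)
    is_ep <- if (req[g]) (hit1 & e2_ind) | (hit2 & e1_ind)
             else (hit1 & e2_all) | (hit2 & e1_all)
    idx <- which(hit)
    data.frame(gene_id = genes$gene_id[g], loop_index = idx,
               span = spans[idx], is_ctcf = is_ctcf[idx], is_ep = is_ep[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out
}

#' Per-gene loop span summary
#'
#' Longest (or mean) loop span per gene among loops passing the filter.
#' Genes without a qualifying loop are included with span 0 for the `all`
#' and `ctcf` filters, and excluded for the `enhancer_promoter` filter
#' (short enhancer-promoter loops below Hi-C resolution cannot be encoded
#' as zero-span observations).
#'
#' @param genes gene table.
#' @param gene_loops output of [gene_loop_table()].
#' @param filter `"all"`, `"ctcf"` or `"enhancer_promoter"`.
#' @param stat `"longest"` or `"mean"`.
#' @return data.frame (`gene_id`, `span`, `n_loops`, `had_loop`); for the
#'   enhancer-promoter filter only genes with at least one qualifying loop
#'   appear.
#' @export
loop_span_per_gene <- function(genes, gene_loops,
                               filter = c("all", "ctcf", "enhancer_promoter"),
                               stat = c("longest", "mean")) {
  filter <- match.arg(filter)
  stat <- match.arg(stat)
  gl <- switch(filter,
               all = gene_loops,
               ctcf = gene_loops[gene_loops$is_ctcf, , drop = FALSE],
               enhancer_promoter = gene_loops[gene_loops$is_ep, , drop = FALSE])
  f <- if (stat == "longest") max else mean
  agg <- if (nrow(gl) > 0L) {
    stats::aggregate(span ~ gene_id, data = gl, FUN = f)
  } else {
    data.frame(gene_id = character(), span = numeric())
  }
  n_agg <- if (nrow(gl) > 0L) {
    stats::aggregate(span ~ gene_id, data = gl, FUN = length)
  } else {
    data.frame(gene_id = character(), span = numeric())
  }
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out$span <- agg$span[match(out$gene_id, agg$gene_id)]
  out$n_loops <- n_agg$span[match(out$gene_id, n_agg$gene_id)]
  out$n_loops[is.na(out$n_loops)] <- 0L
  out$had_loop <- !is.na(out$span)
  if (filter == "enhancer_promoter") {
    out <- out[out$had_loop, , drop = FALSE]
  } else {
    out$span[!out$had_loop] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Assign gene expression classes from differential-expression tables
#'
#' Curated membership lists define IEGs and LRGs. LRGs with adjusted
#' p < `alpha` and negative log2 fold change in both genotype contrasts
#' (silenced and 6 h depolarized) are `downregulated_LRG`; LRGs with
#' adjusted p > `alpha` in both are `non_deregulated_LRG`; LRGs deregulated
#' in exactly one condition are excluded. Genes outside the lists are
#' `inducible` when adjusted p < `alpha` and log2 fold change >=
#' `induction_lfc` in either induction contrast, `constitutive` when
#' expressed with adjusted p >= `alpha` in both induction contrasts, and
#' `other` otherwise.
#'
#' @param genes gene table with per-contrast `padj_*`, `log2fc_*`,
#'   `expressed_*` columns.
#' @param ieg_ids,lrg_ids curated membership id lists (must be disjoint).
#' @param genotype_contrasts length-2 character: the knockout-vs-control
#'   contrast names in silenced (TTX) and 6 h KCl conditions.
#' @param induction_contrasts length-2 character: the KCl-vs-TTX induction
#'   contrast names.
#' @param alpha significance threshold (default 0.05).
#' @param induction_lfc minimum induction log2 fold change (default 1).
#' @return data.frame (`gene_id`, `expression_class`, `reason`): every gene
#'   receives exactly one class, with `reason` set for exclusions.
#' @export
assign_expression_class <- function(genes, ieg_ids, lrg_ids,
                                    genotype_contrasts = c("nex_ttx", "nex_kcl6"),
                                    induction_contrasts = c("kcl1_vs_ttx", "kcl6_vs_ttx"),
                                    alpha = 0.05, induction_lfc = 1) {
  both <- intersect(ieg_ids, lrg_ids)
  if (length(both) > 0L) {
    ls_stop(paste0("gene(s) in both IEG and LRG lists: ", paste(both, collapse = ", ")),
            "loopscore_validation_error")
  }
  for (ct in c(genotype_contrasts, induction_contrasts)) {
    need <- paste0(c("padj_", "log2fc_", "expressed_"), ct)
    miss <- setdiff(need, names(genes))
    if (length(miss) > 0L) {
      ls_stop(paste0("missing contrast column(s) for '", ct, "': ",
                     paste(miss, collapse = ", ")), "loopscore_validation_error")
    }
  }
  col <- function(prefix, ct) genes[[paste0(prefix, ct)]]
  p_gt1 <- col("padj_", genotype_contrasts[1L])
  p_gt2 <- col("padj_", genotype_contrasts[2L])
  f_gt1 <- col("log2fc_", genotype_contrasts[1L])
  f_gt2 <- col("log2fc_", genotype_contrasts[2L])
  p_in1 <- col("padj_", induction_contrasts[1L])
  p_in2 <- col("padj_", induction_contrasts[2L])
  f_in1 <- col("log2fc_", induction_contrasts[1L])
  f_in2 <- col("log2fc_", induction_contrasts[2L])
  expressed <- col("expressed_", induction_contrasts[1L]) &
    col("expressed_", induction_contrasts[2L])

  n <- nrow(genes)
  class <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  is_ieg <- genes$gene_id %in% ieg_ids
  is_lrg <- genes$gene_id %in% lrg_ids

  class[is_ieg] <- "IEG"
  lrg_missing <- is_lrg & (is.na(p_gt1) | is.na(p_gt2))
  class[lrg_missing] <- "excluded"
  reason[lrg_missing] <- "no assigned p-value in a genotype contrast"
  down <- is_lrg & !lrg_missing & p_gt1 < alpha & p_gt2 < alpha & f_gt1 < 0 & f_gt2 < 0
  nond <- is_lrg & !lrg_missing & p_gt1 > alpha & p_gt2 > alpha
  class[down] <- "downregulated_LRG"
  class[nond] <- "non_deregulated_LRG"
  rest_lrg <- is_lrg & is.na(class)
  class[rest_lrg] <- "excluded"
  reason[rest_lrg] <- "deregulated in one condition only (or discordant sign)"

  plain <- !is_ieg & !is_lrg
  ind_ok <- !is.na(p_in1) & !is.na(p_in2)
  inducible <- plain & ind_ok &
    ((p_in1 < alpha & f_in1 >= induction_lfc) | (p_in2 < alpha & f_in2 >= induction_lfc))
  class[inducible] <- "inducible"
  constit <- plain & is.na(class) & ind_ok & expressed %in% TRUE &
    p_in1 >= alpha & p_in2 >= alpha
  class[constit] <- "constitutive"
  other <- plain & is.na(class)
  class[other] <- "other"
  reason[other] <- "no class rule applies (unexpressed, missing or intermediate statistics)"

  data.frame(gene_id = genes$gene_id, expression_class = class,
             reason = reason, stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. By default the
#' p-value follows `stats::ks.test`'s convention (exact small-sample p when
#' `m * n < 10^4` and there are no ties, asymptotic Kolmogorov distribution
#' with effective n = mn/(m+n) otherwise); `exact = FALSE` forces the
#' asymptotic form.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact passed to [stats::ks.test()] (NULL = its default rule).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b, exact = NULL) {
  if (length(a) < 1L || length(b) < 1L) {
    ls_stop("ks_two_sample needs non-empty samples", "loopscore_validation_error")
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Odds ratio is the sample cross-product ratio (a*d)/(b*c), infinite when
#' b*c = 0 and a*d > 0. The two-tailed p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (via [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integers with positive margins.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0)) {
    ls_stop("negative entries in 2x2 table", "loopscore_validation_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    ls_stop("2x2 table has a zero margin", "loopscore_validation_error")
  }
  a <- table[1L, 1L]; b <- table[1L, 2L]; c <- table[2L, 1L]; d <- table[2L, 2L]
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p = p)
}

#' Promoter peak-binding enrichment
#'
#' A gene's promoter is "bound" iff at least one peak overlaps
#' `[TSS - halfwidth, TSS + halfwidth)`. Builds the 2x2 bound/unbound x
#' interest/background table and applies the two-tailed Fisher exact test.
#' The promoter halfwidth is a documented default, not a value stated by
#' the study.
#'
#' @param genes_of_interest,background_genes disjoint gene tables.
#' @param peaks peak table.
#' @param promoter_halfwidth promoter window half-width in bp (default 2000).
#' @return list with `table` (2x2), `odds_ratio`, `p`.
#' @export
promoter_binding_enrichment <- function(genes_of_interest, background_genes,
                                        peaks, promoter_halfwidth = 2000) {
  if (nrow(background_genes) == 0L) {
    ls_stop("empty background gene set", "loopscore_validation_error")
  }
  shared <- intersect(genes_of_interest$gene_id, background_genes$gene_id)
  if (length(shared) > 0L) {
    ls_stop("gene sets overlap; interest and background must be disjoint",
            "loopscore_validation_error")
  }
  bound <- function(g) {
    prom <- data.frame(chrom = g$chrom,
                       start = pmax(0, g$tss - promoter_halfwidth),
                       end = g$tss + promoter_halfwidth)
    any_overlap(prom, peaks)
  }
  bi <- bound(genes_of_interest)
  bb <- bound(background_genes)
  tab <- matrix(c(sum(bi), sum(bb), sum(!bi), sum(!bb)), nrow = 2L, byrow = TRUE,
                dimnames = list(c("bound", "unbound"), c("interest", "background")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}
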