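# Synthetic-data generators. These define the study conditions under which the
# whole pipeline is exercised: multi-replicate, multi-condition 5C primer-pair
# counts with power-law distance decay, multiplicative primer biases,
# negative-binomial noise, planted constitutive/inducible loops and PCR-bias
# spikes; and a gene/loop/peak/DE fixture with a planted loop-span versus
# dysregulation relationship.

#' Default experimental conditions
#'
#' Four conditions emulating silenced (TTX) and depolarized (KCl) neurons,
#' each with and without cohesin (RAD21) depletion. `stimulated` gates
#' inducible planted loops; `depleted` removes the enrichment of
#' cohesin-dependent (CTCF) planted loops.
#'
#' @return data.frame with columns `name`, `stimulated`, `depleted`.
#' @export
default_conditions <- function() {
  data.frame(name = c("TTX", "KCl", "TTX_RAD21dep", "KCl_RAD21dep"),
             stimulated = c(FALSE, TRUE, FALSE, TRUE),
             depleted = c(FALSE, FALSE, TRUE, TRUE),
             stringsAsFactors = FALSE)
}

#' Default planted loops for the packaged simulation
#'
#' Three archetypes mirroring the locus biology the pipeline is meant to
#' resolve: a short-range inducible enhancer-promoter loop that is robust to
#' cohesin depletion (Fos/Arc-like), a constitutive CTCF/cohesin-dependent
#' domain loop, and a long-range inducible cohesin-dependent loop (Bdnf-like).
#'
#' @return data.frame with columns `name`, `bin_i`, `bin_j`, `fold`,
#'   `inducible`, `ctcf`.
#' @export
default_planted_loops <- function() {
  data.frame(name = c("ep_short_inducible", "ctcf_constitutive", "ep_long_ctcf"),
             bin_i = c(30L, 10L, 15L),
             bin_j = c(38L, 60L, 85L),
             fold = c(4, 3, 4),
             inducible = c(TRUE, FALSE, TRUE),
             ctcf = c(FALSE, TRUE, TRUE),
             stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic 5C counts
#'
#' Defaults are the packaged study conditions: one 400 kb region (a
#' desk-scale stand-in for typical multi-megabase 5C regions), HindIII-
#' like ~2 kb fragments, 4 kb bins, contact probability decaying as
#' d^-decay_exponent, log-normal per-primer biases, negative-binomial counts,
#' two replicates for each of four conditions, and the planted loops of
#' [default_planted_loops()].
#'
#' @param region_length region size in bp (>= 10 bins).
#' @param chrom chromosome name used for all synthetic coordinates.
#' @param mean_fragment_length mean restriction-fragment length in bp (>= 500).
#' @param bin_size bin size in bp (default 4000).
#' @param window binning window in bp (default 12000).
#' @param decay_exponent power-law exponent alpha of contact decay (> 0).
#' @param library_size expected total read-pair count per replicate.
#' @param bias_sd standard deviation of log per-primer bias.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param planted_loops data.frame as in [default_planted_loops()], or NULL.
#' @param loop_halo_bins sets the half-width (`loop_halo_bins * bin_size +
#'   bin_size / 2`) of the anchor window within which fragments receive the
#'   planted loop enrichment. The default, `window/bin_size %/% 2`, makes
#'   that window coincide with the binning window, so the planted fold is
#'   realized exactly at the loop's center pixel after binning.
#' @param spike_pairs data.frame (`i`, `j`, `fold`) of primer pairs receiving
#'   PCR-bias spikes, or NULL to draw `n_spikes` random distal queryable
#'   pairs per replicate.
#' @param n_spikes,spike_fold number and fold of automatic spikes.
#' @param n_replicates replicates per condition (>= 1).
#' @param conditions data.frame as in [default_conditions()].
#' @param seed master seed; all sub-streams derive from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(region_length = 400000,
                       chrom = "chrS",
                       mean_fragment_length = 2000,
                       bin_size = 4000,
                       window = 12000,
                       decay_exponent = 1,
                       library_size = 2e6,
                       bias_sd = 0.3,
                       dispersion = 0.1,
                       planted_loops = default_planted_loops(),
                       loop_halo_bins = NULL,
                       spike_pairs = NULL,
                       n_spikes = 4,
                       spike_fold = 50,
                       n_replicates = 2,
                       conditions = default_conditions(),
                       seed = 1) {
  if (is.null(loop_halo_bins)) loop_halo_bins <- (window %/% bin_size) %/% 2L
  cfg <- list(region_length = region_length, chrom = chrom,
              mean_fragment_length = mean_fragment_length,
              bin_size = bin_size, window = window,
              decay_exponent = decay_exponent, library_size = library_size,
              bias_sd = bias_sd, dispersion = dispersion,
              planted_loops = planted_loops, loop_halo_bins = loop_halo_bins,
              spike_pairs = spike_pairs, n_spikes = n_spikes,
              spike_fold = spike_fold, n_replicates = n_replicates,
              conditions = conditions, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$region_length < 10 * cfg$bin_size) {
    ls_stop("region_length must be at least 10 bins", "loopscore_config_error")
  }
  if (cfg$mean_fragment_length < 500) {
    ls_stop("mean_fragment_length must be >= 500 bp", "loopscore_config_error")
  }
  if (cfg$n_replicates < 1) {
    ls_stop("n_replicates must be >= 1", "loopscore_config_error")
  }
  if (cfg$decay_exponent <= 0) {
    ls_stop("decay_exponent must be > 0", "loopscore_config_error")
  }
  pl <- cfg$planted_loops
  if (!is.null(pl) && nrow(pl) > 0L) {
    if (any(pl$fold < 1)) {
      ls_stop("planted loop enrichment_fold must be >= 1", "loopscore_config_error")
    }
    n_bins <- ceiling(cfg$region_length / cfg$bin_size)
    if (any(pl$bin_i < 1 | pl$bin_j < 1 | pl$bin_i > n_bins | pl$bin_j > n_bins)) {
      ls_stop("planted loop anchor bin outside the region", "loopscore_config_error")
    }
  }
  invisible(cfg)
}

#' Simulate restriction fragments tiling a region
#'
#' Contiguous, non-overlapping fragments over `[0, region_length)` with
#' geometric-like (shifted-exponential) lengths around the configured mean,
#' emulating a HindIII digest. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return interval data.frame (`chrom`, `start`, `end`).
#' @export
simulate_fragments <- function(config) {
  min_len <- 200
  mean_len <- config$mean_fragment_length
  with_substream(config$seed, "fragments", {
    n_guess <- ceiling(config$region_length / mean_len * 2) + 8L
    lens <- min_len + round(stats::rexp(n_guess, rate = 1 / (mean_len - min_len)))
    while (sum(lens) < config$region_length) {
      lens <- c(lens, min_len + round(stats::rexp(n_guess, rate = 1 / (mean_len - min_len))))
    }
    ends <- cumsum(lens)
    ends <- c(ends[ends < config$region_length], config$region_length)
    starts <- c(0, ends[-length(ends)])
    # merge an undersized trailing sliver into the previous fragment
    if (length(ends) > 1L && (ends[length(ends)] - starts[length(starts)]) < min_len) {
      starts <- starts[-length(starts)]
      ends <- ends[-(length(ends) - 1L)]
    }
    if (length(ends) < 4L) {
      ls_stop("region too short for >= 4 fragments", "loopscore_config_error")
    }
    genomic_intervals(config$chrom, starts, ends)
  })
}

#' Design 5C primers over a fragment set (double-alternating scheme)
#'
#' Each fragment receives one primer; orientations cycle FOR, LREV, REV, LFOR
#' along the region, so forward-sense (FOR/LFOR) and reverse-sense (REV/LREV)
#' primers alternate and adjacent fragments form queryable pairs. A primer
#' pair is queryable iff one member is forward-sense and the other
#' reverse-sense.
#'
#' @param fragments fragment intervals from [simulate_fragments()].
#' @return object of class `primer_design`: list with `primers` (primer_id,
#'   fragment_index, orientation, chrom, start, end) and `fragments`.
#' @export
design_primers <- function(fragments) {
  n <- nrow(fragments)
  if (n < 4L) ls_stop("need >= 4 fragments to design primers", "loopscore_config_error")
  cycle <- c("FOR", "LREV", "REV", "LFOR")
  orientation <- cycle[((seq_len(n) - 1L) %% 4L) + 1L]
  p_start <- fragments$start
  p_end <- pmin(fragments$start + 30, fragments$end)
  primers <- data.frame(primer_id = paste0(orientation, "_", seq_len(n)),
                        fragment_index = seq_len(n),
                        orientation = orientation,
                        chrom = fragments$chrom,
                        start = p_start, end = p_end,
                        stringsAsFactors = FALSE)
  structure(list(primers = primers, fragments = fragments),
            class = "primer_design")
}

#' Forward/reverse primer sense and pair queryability
#'
#' @param orientation character vector of orientations.
#' @return `is_forward_sense`: logical. `queryable_pair`: TRUE iff the two
#'   orientations have opposite sense.
#' @export
is_forward_sense <- function(orientation) orientation %in% c("FOR", "LFOR")

#' @rdname is_forward_sense
#' @param o1,o2 orientations of the two primers.
#' @export
queryable_pair <- function(o1, o2) xor(is_forward_sense(o1), is_forward_sense(o2))

# Per-condition effective enrichment of a planted loop: inducible loops are
# enriched only in stimulated conditions; CTCF (cohesin-dependent) loops lose
# their enrichment in depleted conditions.
loop_fold_in_condition <- function(loop, condition) {
  active <- (!loop$inducible | condition$stimulated) &
    (!loop$ctcf | !condition$depleted)
  ifelse(active, loop$fold, 1)
}

#' Simulate primer-level 5C count matrices
#'
#' For each queryable primer pair (i, j) the expected count is
#' `library_size * Z^-1 * d_ij^-alpha * b_i * b_j * L_ij(condition)`, where
#' `d_ij` is the fragment-midpoint distance floored at one bin, `b` are
#' log-normal primer biases (shared across replicates: primer efficiency is a
#' design property), `L_ij` the planted-loop enrichment active in that
#' condition, and Z normalizes the total expectation to `library_size`.
#' Counts are negative binomial with the configured dispersion; PCR-bias
#' spikes multiply the drawn counts of selected pairs. Non-queryable pairs
#' are non-informative; matrices are exactly symmetric and deterministic
#' under the config seed.
#'
#' @param config a [sim_config()].
#' @param design a [design_primers()] result consistent with `config`.
#' @return named list `<condition>.<replicate>` of primer-level
#'   [contact_matrix()] objects, with attribute `meta` (condition/replicate
#'   table) and attribute `biases`.
#' @export
simulate_counts <- function(config, design) {
  validate_sim_config(config)
  frags <- design$fragments
  if (max(frags$end) > config$region_length) {
    ls_stop("design extends beyond the configured region", "loopscore_config_error")
  }
  n <- nrow(design$primers)
  mids <- midpoint(frags)[design$primers$fragment_index]
  d <- abs(outer(mids, mids, "-"))
  d <- pmax(d, config$bin_size) # distance floor of one bin
  fwd <- is_forward_sense(design$primers$orientation)
  queryable <- outer(fwd, fwd, FUN = xor)
  diag(queryable) <- FALSE

  bias <- with_substream(config$seed, "biases",
                         exp(stats::rnorm(n, 0, config$bias_sd)))

  base_decay <- d^(-config$decay_exponent) * outer(bias, bias)

  # A fragment belongs to a planted anchor iff it overlaps the same
  # half-open window the binning stage uses around the anchor bin's center
  # (half-width halo_bins * bin_size + bin_size / 2), so the planted fold is
  # realized exactly at the loop's center pixel after binning.
  half_w <- config$loop_halo_bins * config$bin_size + config$bin_size / 2
  fr <- frags[design$primers$fragment_index, , drop = FALSE]
  anchor_members <- function(b) {
    c0 <- (b - 0.5) * config$bin_size
    fr$start < c0 + half_w & fr$end > c0 - half_w
  }
  loop_mask <- function(loop) {
    ri <- anchor_members(loop$bin_i)
    rj <- anchor_members(loop$bin_j)
    outer(ri, rj) | outer(rj, ri)
  }

  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = config$conditions$name,
                      stringsAsFactors = FALSE)[, c(2L, 1L)]
  out <- vector("list", nrow(meta))
  names(out) <- paste(meta$condition, meta$replicate, sep = ".")
  up <- which(queryable & upper.tri(queryable), arr.ind = TRUE)

  for (r in seq_len(nrow(meta))) {
    cond <- config$conditions[config$conditions$name == meta$condition[r], ]
    L <- matrix(1, n, n)
    pl <- config$planted_loops
    if (!is.null(pl) && nrow(pl) > 0L) {
      for (k in seq_len(nrow(pl))) {
        f <- loop_fold_in_condition(pl[k, ], cond)
        if (f != 1) {
          m <- loop_mask(pl[k, ])
          L[m] <- L[m] * f
        }
      }
    }
    W <- base_decay * L
    mu_up <- config$library_size * W[up] / sum(W[up])
    key <- sprintf("counts/%s/%d", meta$condition[r], meta$replicate[r])
    counts_up <- with_substream(config$seed, key, {
      if (config$dispersion > 0) {
        stats::rnbinom(length(mu_up), mu = mu_up, size = 1 / config$dispersion)
      } else {
        stats::rpois(length(mu_up), mu_up)
      }
    })
    v <- matrix(0, n, n)
    v[up] <- counts_up
    # PCR-bias spikes, applied after the draw
    sp <- config$spike_pairs
    if (is.null(sp) && config$n_spikes > 0) {
      sp <- with_substream(config$seed, paste0("spikes/", key), {
        distal <- up[d[up] >= 10 * config$bin_size, , drop = FALSE]
        pick <- sample(nrow(distal), min(config$n_spikes, nrow(distal)))
        data.frame(i = distal[pick, 1L], j = distal[pick, 2L],
                   fold = config$spike_fold)
      })
    }
    if (!is.null(sp) && nrow(sp) > 0L) {
      ii <- pmin(sp$i, sp$j)
      jj <- pmax(sp$i, sp$j)
      ok <- queryable[cbind(ii, jj)]
      v[cbind(ii, jj)[ok, , drop = FALSE]] <-
        round(pmax(v[cbind(ii, jj)[ok, , drop = FALSE]], 1) * sp$fold[ok])
    }
    v <- v + t(v)
    v[!queryable] <- NA_real_
    out[[r]] <- contact_matrix(v, queryable,
                               design$primers[, c("chrom", "start", "end")],
                               level = "primer")
  }
  attr(out, "meta") <- meta
  attr(out, "biases") <- bias
  out
}

#' Simulate a bin-level contact matrix with planted loops
#'
#' A direct bin-resolution generator used to characterize the scoring stage:
#' expected values follow `scale * |i - j|^-alpha` with optional
#' negative-binomial noise, and planted loops multiply the expectation of
#' single pixels. The diagonal is non-informative.
#'
#' @param n_bins number of bins.
#' @param bin_size bin width in bp (axis coordinates only).
#' @param scale expected value at one-bin separation.
#' @param alpha decay exponent.
#' @param dispersion negative-binomial dispersion; 0 returns the noiseless
#'   expectation.
#' @param loops data.frame (`i`, `j`, `fold`) of planted pixels, or NULL.
#' @param seed RNG seed (ignored when `dispersion = 0`).
#' @return a bin-level [contact_matrix()].
#' @export
simulate_binned_matrix <- function(n_bins, bin_size = 4000, scale = 1000,
                                   alpha = 1, dispersion = 0.05, loops = NULL,
                                   seed = 1) {
  dd <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  mu <- scale * pmax(dd, 1)^(-alpha)
  if (!is.null(loops) && nrow(loops) > 0L) {
    for (k in seq_len(nrow(loops))) {
      i <- loops$i[k]; j <- loops$j[k]
      mu[i, j] <- mu[i, j] * loops$fold[k]
      mu[j, i] <- mu[j, i] * loops$fold[k]
    }
  }
  informative <- dd >= 1L
  if (dispersion > 0) {
    up <- which(upper.tri(mu) & informative, arr.ind = TRUE)
    v <- matrix(0, n_bins, n_bins)
    v[up] <- with_substream(seed, "binned",
                            stats::rnbinom(nrow(up), mu = mu[up], size = 1 / dispersion))
    v <- v + t(v)
  } else {
    v <- mu
  }
  v[!informative] <- NA_real_
  axis <- genomic_intervals("chrS", (seq_len(n_bins) - 1L) * bin_size,
                            seq_len(n_bins) * bin_size)
  contact_matrix(v, informative, axis, level = "bin")
}

#' Configuration for the gene/loop/peak/DE fixture
#'
#' Class sizes default to the study's comparison groups (18 IEGs, 22
#' downregulated LRGs, 43 non-deregulated LRGs) plus a constitutive
#' background set. Loop spans are log-normal per class; by default
#' downregulated LRGs are planted with long loops (median 500 kb) and
#' non-deregulated LRGs with short ones (median 100 kb).
#'
#' @param n_ieg,n_down_lrg,n_nondereg_lrg,n_constitutive class sizes.
#' @param span_median named numeric, median loop span in bp per class.
#' @param span_sdlog log-sd of the span distributions.
#' @param loops_per_gene integer vector sampled uniformly per gene.
#' @param ctcf_anchor_frac fraction of loop anchors receiving a CTCF peak.
#' @param enhancer_loop_frac fraction of loops whose distal anchor receives
#'   an enhancer.
#' @param genotype_contrasts names of the knockout-vs-control contrasts in
#'   silenced and 6 h depolarized conditions.
#' @param induction_contrasts names of the KCl-vs-TTX induction contrasts.
#' @param gene_spacing distance between successive TSSs in bp.
#' @param anchor_width loop anchor width in bp.
#' @param seed master seed.
#' @return list of class `gene_loop_config`.
#' @export
gene_loop_config <- function(n_ieg = 18, n_down_lrg = 22, n_nondereg_lrg = 43,
                             n_constitutive = 60,
                             span_median = c(IEG = 5e4, down_lrg = 5e5,
                                             nondereg_lrg = 1e5, constitutive = 1.5e5),
                             span_sdlog = 0.6,
                             loops_per_gene = 1:3,
                             ctcf_anchor_frac = 0.7,
                             enhancer_loop_frac = 0.6,
                             genotype_contrasts = c("nex_ttx", "nex_kcl6"),
                             induction_contrasts = c("kcl1_vs_ttx", "kcl6_vs_ttx"),
                             gene_spacing = 6e6,
                             anchor_width = 1e4,
                             seed = 1) {
  stopifnot(n_ieg >= 0, n_down_lrg >= 0, n_nondereg_lrg >= 0, n_constitutive >= 0,
            all(span_median > 0), span_sdlog > 0)
  structure(list(n_ieg = n_ieg, n_down_lrg = n_down_lrg,
                 n_nondereg_lrg = n_nondereg_lrg, n_constitutive = n_constitutive,
                 span_median = span_median, span_sdlog = span_sdlog,
                 loops_per_gene = loops_per_gene,
                 ctcf_anchor_frac = ctcf_anchor_frac,
                 enhancer_loop_frac = enhancer_loop_frac,
                 genotype_contrasts = genotype_contrasts,
                 induction_contrasts = induction_contrasts,
                 gene_spacing = gene_spacing, anchor_width = anchor_width,
                 seed = seed),
            class = "gene_loop_config")
}

#' Simulate the gene/loop/peak/enhancer/DE fixture
#'
#' Places one TSS per gene along a synthetic chromosome; gives each gene 1-3
#' loops whose proximal anchor contains the TSS and whose spans are drawn
#' from the gene class's distribution (truncated to keep anchors
#' non-overlapping and genes independent); places CTCF peaks in a
#' configurable fraction of anchors and enhancers in distal anchors;
#' and emits differential-expression columns that satisfy the
#' [assign_expression_class()] rules for the planted class by construction.
#'
#' @param config a [gene_loop_config()].
#' @return list with `genes` (gene table), `loops` (BEDPE-style loop table),
#'   `peaks`, `enhancers`, and the curated id lists `ieg`, `lrg`.
#' @export
simulate_gene_loop_fixture <- function(config) {
  classes <- c(rep("IEG", config$n_ieg),
               rep("down_lrg", config$n_down_lrg),
               rep("nondereg_lrg", config$n_nondereg_lrg),
               rep("constitutive", config$n_constitutive))
  n <- length(classes)
  empty_genes <- data.frame(gene_id = character(), chrom = character(),
                            tss = numeric(), class_label = character(),
                            stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(genes = empty_genes,
                loops = data.frame(chrom = character(), start1 = numeric(),
                                   end1 = numeric(), start2 = numeric(),
                                   end2 = numeric(), name = character()),
                peaks = data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), label = character(),
                                   inducible = logical()),
                enhancers = data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), label = character(),
                                       inducible = logical()),
                ieg = character(), lrg = character()))
  }
  prefix <- c(IEG = "IEG", down_lrg = "DLRG", nondereg_lrg = "NLRG",
              constitutive = "CONST")
  idx_in_class <- stats::ave(seq_len(n), classes, FUN = seq_along)
  gene_id <- sprintf("%s_%02d", prefix[classes], idx_in_class)
  tss <- config$gene_spacing / 2 + (seq_len(n) - 1L) * config$gene_spacing
  hw <- config$anchor_width / 2
  span_cap <- config$gene_spacing - config$anchor_width - 1e5
  span_floor <- 2.5 * config$anchor_width

  loops <- list(); peaks <- list(); enh <- list()
  with_substream(config$seed, "gene_loops", {
    for (g in seq_len(n)) {
      k <- if (length(config$loops_per_gene) == 1L) config$loops_per_gene
           else sample(config$loops_per_gene, 1L)
      med <- config$span_median[[classes[g]]]
      spans <- pmin(pmax(stats::rlnorm(k, log(med), config$span_sdlog),
                         span_floor), span_cap)
      for (s in spans) {
        a1 <- c(tss[g] - hw, tss[g] + hw)
        m2 <- tss[g] + round(s)
        a2 <- c(m2 - hw, m2 + hw)
        loops[[length(loops) + 1L]] <- data.frame(
          chrom = "chrF", start1 = a1[1L], end1 = a1[2L],
          start2 = a2[1L], end2 = a2[2L],
          name = sprintf("%s_loop%d", gene_id[g], length(loops) + 1L),
          stringsAsFactors = FALSE)
        for (anchor in list(a1, a2)) {
          if (stats::runif(1) < config$ctcf_anchor_frac) {
            c0 <- mean(anchor)
            peaks[[length(peaks) + 1L]] <- data.frame(
              chrom = "chrF", start = c0 - 250, end = c0 + 250,
              label = "CTCF", inducible = NA, stringsAsFactors = FALSE)
          }
        }
        if (stats::runif(1) < config$enhancer_loop_frac) {
          c0 <- mean(a2)
          # ARG enhancers are activity-induced; constitutive genes get a mix
          ind <- if (classes[g] == "constitutive") stats::runif(1) < 0.5 else TRUE
          enh[[length(enh) + 1L]] <- data.frame(
            chrom = "chrF", start = c0 - 500, end = c0 + 500,
            label = "enhancer", inducible = ind, stringsAsFactors = FALSE)
        }
      }
    }
  })

  de <- with_substream(config$seed, "de_tables", {
    cols <- list()
    gt <- config$genotype_contrasts
    ic <- config$induction_contrasts
    runifn <- function(lo, hi) stats::runif(n, lo, hi)
    for (ct in gt) {
      padj <- numeric(n); lfc <- numeric(n)
      down <- classes == "down_lrg"
      padj[down] <- stats::runif(sum(down), 1e-4, 0.04)
      lfc[down] <- stats::runif(sum(down), -2.5, -0.5)
      nd <- classes %in% c("nondereg_lrg", "constitutive")
      padj[nd] <- stats::runif(sum(nd), 0.1, 0.95)
      lfc[nd] <- stats::runif(sum(nd), -0.3, 0.3)
      ieg <- classes == "IEG"
      if (ct == gt[1L]) { # silenced condition: IEGs depend on cohesin
        padj[ieg] <- stats::runif(sum(ieg), 1e-4, 0.04)
        lfc[ieg] <- stats::runif(sum(ieg), -2, -0.5)
      } else { # stimulation normalizes IEG expression
        padj[ieg] <- stats::runif(sum(ieg), 0.1, 0.95)
        lfc[ieg] <- stats::runif(sum(ieg), -0.3, 0.3)
      }
      cols[[paste0("log2fc_", ct)]] <- round(lfc, 4)
      cols[[paste0("padj_", ct)]] <- signif(padj, 4)
      cols[[paste0("expressed_", ct)]] <- rep(TRUE, n)
    }
    for (ct in ic) {
      arg <- classes %in% c("IEG", "down_lrg", "nondereg_lrg")
      padj <- numeric(n); lfc <- numeric(n)
      padj[arg] <- stats::runif(sum(arg), 1e-5, 0.04)
      lfc[arg] <- stats::runif(sum(arg), 1, 4)
      padj[!arg] <- stats::runif(sum(!arg), 0.1, 0.95)
      lfc[!arg] <- stats::runif(sum(!arg), -0.4, 0.4)
      cols[[paste0("log2fc_", ct)]] <- round(lfc, 4)
      cols[[paste0("padj_", ct)]] <- signif(padj, 4)
      cols[[paste0("expressed_", ct)]] <- rep(TRUE, n)
    }
    as.data.frame(cols, check.names = FALSE)
  })

  genes <- cbind(data.frame(gene_id = gene_id, chrom = "chrF", tss = tss,
                            class_label = classes, stringsAsFactors = FALSE),
                 de)
  bind <- function(lst, empty) if (length(lst) > 0L) do.call(rbind, lst) else empty
  list(genes = genes,
       loops = bind(loops, data.frame(chrom = character(), start1 = numeric(),
                                      end1 = numeric(), start2 = numeric(),
                                      end2 = numeric(), name = character())),
       peaks = bind(peaks, data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), label = character(),
                                      inducible = logical())),
       enhancers = bind(enh, data.frame(chrom = character(), start = numeric(),
                                        end = numeric(), label = character(),
                                        inducible = logical())),
       ieg = gene_id[classes == "IEG"],
       lrg = gene_id[classes %in% c("down_lrg", "nondereg_lrg")])
}
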