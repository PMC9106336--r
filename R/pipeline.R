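# Configuration-driven orchestration of the two analyses, with manifests and
# deterministic outputs.

#' Load a pipeline configuration
#'
#' @param config a list, or the path of a YAML file.
#' @return the configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      ls_stop(paste0("config file not found: ", config), "loopscore_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  config
}

#' Path of the packaged synthetic pipeline configurations
#'
#' @param which `"fivec"` or `"loopspan"`.
#' @return file path inside the installed package.
#' @export
packaged_config <- function(which = c("fivec", "loopspan")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, "_config.yaml"), package = "loopscore",
              mustWork = TRUE)
}

sim_config_from_list <- function(sim, seed) {
  args <- sim
  if (!is.null(args$planted_loops)) {
    args$planted_loops <- as.data.frame(do.call(rbind, lapply(args$planted_loops, as.data.frame)))
  }
  if (!is.null(args$conditions)) {
    args$conditions <- as.data.frame(do.call(rbind, lapply(args$conditions, as.data.frame)))
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

manifest_hash <- function(manifest) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, outdir) {
  manifest$manifest_hash <- manifest_hash(manifest)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

write_tsv_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# manifest: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the 5C interaction-score pipeline end-to-end
#'
#' Stages, in fixed order: simulate/tally primer counts, outlier removal,
#' fragment conversion, 4 kb binning, ICE balancing, quantile normalization
#' across all replicates, donut expected + logistic interaction scores, and
#' loop-pixel quantification of the configured (planted) loops per
#' condition. All parameters and per-stage counts are recorded in
#' `manifest.json`; every output table carries the manifest hash. A rerun
#' with identical config and inputs is bit-identical.
#'
#' @param config configuration list or YAML path (see the packaged
#'   `fivec_config.yaml` for the schema).
#' @param outdir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return invisibly, a list with the score maps, quantification table,
#'   manifest and artifact paths.
#' @export
run_5c_pipeline <- function(config, outdir, seed = NULL) {
  config <- load_config(config)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  p <- function(name, default) if (!is.null(stages[[name]])) stages[[name]] else default
  bin_size <- p("bin_size", 4000)
  window <- p("window", 12000)
  if (window < bin_size) {
    ls_stop("invalid config: window < bin_size", "loopscore_config_error")
  }
  outlier_fold <- p("outlier_fold", 8)
  ice_tol <- p("ice_tol", 1e-8)
  ice_max_iter <- p("ice_max_iter", 500)
  min_separation <- p("min_separation", 1)
  donut_w <- p("donut_width", 5)
  donut_p <- p("donut_exclusion", 2)
  min_ring <- p("min_ring_pixels", 10)
  p_floor <- p("p_floor", 1e-12)
  if (donut_w <= donut_p) {
    ls_stop("invalid config: donut_width <= donut_exclusion", "loopscore_config_error")
  }
  scfg <- sim_config_from_list(config$simulation, seed)
  scfg$bin_size <- bin_size
  scfg$window <- window

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      ls_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "loopscore_stage_error")
    })
    res
  }

  stage_counts <- list()
  frags <- run_stage("simulate", simulate_fragments(scfg))
  design <- run_stage("simulate", design_primers(frags))
  mats <- run_stage("tally", simulate_counts(scfg, design))
  meta <- attr(mats, "meta")
  stage_counts$tally <- list(n_matrices = length(mats),
                             pairs_tallied = vapply(mats, function(m)
                               sum(m$values[cm_upper_pairs(m)]), numeric(1L)))

  filtered <- run_stage("outlier", lapply(mats, remove_outliers, fold = outlier_fold))
  stage_counts$outlier <- list(outliers_removed =
                                 vapply(filtered, function(x) nrow(x$removed), numeric(1L)))
  frag_mats <- run_stage("fragment",
                         lapply(filtered, function(x) primer_to_fragment(x$matrix, design)))
  stage_counts$fragment <- list(informative_pairs =
                                  vapply(frag_mats, function(m) nrow(cm_upper_pairs(m)), numeric(1L)))
  bin_mats <- run_stage("bin", lapply(frag_mats, bin_to_grid,
                                      bin_size = bin_size, window = window))
  stage_counts$bin <- list(n_bins = nrow(bin_mats[[1L]]$values),
                           informative_pixels =
                             vapply(bin_mats, function(m) nrow(cm_upper_pairs(m)), numeric(1L)))
  iced <- run_stage("ice", lapply(bin_mats, ice_balance, tol = ice_tol,
                                  max_iter = ice_max_iter,
                                  min_separation = min_separation))
  stage_counts$ice <- list(iterations = vapply(iced, `[[`, numeric(1L), "n_iterations"),
                           converged = vapply(iced, `[[`, logical(1L), "converged"))
  normed <- run_stage("quantile_normalize",
                      quantile_normalize(lapply(iced, `[[`, "matrix")))
  names(normed) <- names(mats)
  stage_counts$quantile_normalize <- list(common_pixels = nrow(cm_upper_pairs(normed[[1L]])))

  score_one <- function(m) {
    exp_m <- donut_expected(m, w = donut_w, p_excl = donut_p, min_ring = min_ring)
    list(expected = exp_m, scores = score_matrix(m, exp_m, p_floor = p_floor))
  }
  scored <- run_stage("score", lapply(normed, score_one))
  stage_counts$score <- list(pixels_scored = vapply(scored, function(s)
    sum(!is.na(s$scores$score)), numeric(1L)))

  # condition-level observed matrix and expected model (mean over replicates)
  conditions <- unique(meta$condition)
  cond_mats <- lapply(conditions, function(cn) {
    reps <- normed[meta$condition == cn]
    v <- Reduce(`+`, lapply(reps, `[[`, "values")) / length(reps)
    contact_matrix(v, reps[[1L]]$informative, reps[[1L]]$axis, "bin")
  })
  names(cond_mats) <- conditions

  loops <- scfg$planted_loops
  quant <- NULL
  if (!is.null(loops) && nrow(loops) > 0L) {
    bins <- cond_mats[[1L]]$axis
    rows <- list()
    for (k in seq_len(nrow(loops))) {
      aA <- bins[loops$bin_i[k], , drop = FALSE]
      aB <- bins[loops$bin_j[k], , drop = FALSE]
      for (cn in conditions) {
        exp_c <- donut_expected(cond_mats[[cn]], w = donut_w, p_excl = donut_p,
                                min_ring = min_ring)
        q <- quantify_loop_pixels(cond_mats[[cn]], aA, aB)
        dc <- distance_corrected_loop_strength(cond_mats[[cn]], exp_c, aA, aB)
        rows[[length(rows) + 1L]] <- data.frame(
          loop = loops$name[k], condition = cn,
          observed_mean = q$mean, n_pixels = q$n_pixels,
          distance_corrected_strength = dc$ratio)
      }
    }
    quant <- do.call(rbind, rows)
  }
  stage_counts$loop_quantification <- list(n_rows = if (is.null(quant)) 0L else nrow(quant))

  manifest <- list(
    pipeline = "5c_interaction_scores",
    package_version = as.character(utils::packageVersion("loopscore")),
    seed = scfg$seed,
    parameters = list(bin_size = bin_size, window = window,
                      outlier_fold = outlier_fold, ice_tol = ice_tol,
                      ice_max_iter = ice_max_iter, min_separation = min_separation,
                      donut_width = donut_w, donut_exclusion = donut_p,
                      min_ring_pixels = min_ring, p_floor = p_floor,
                      region_length = scfg$region_length,
                      library_size = scfg$library_size,
                      n_replicates = scfg$n_replicates,
                      conditions = scfg$conditions$name),
    stages = list(
      list(name = "tally", counts = stage_counts$tally),
      list(name = "outlier_removal", counts = stage_counts$outlier),
      list(name = "fragment_conversion", counts = stage_counts$fragment),
      list(name = "binning", counts = stage_counts$bin),
      list(name = "ice_balancing", counts = stage_counts$ice),
      list(name = "quantile_normalization", counts = stage_counts$quantile_normalize),
      list(name = "scoring", counts = stage_counts$score),
      list(name = "loop_quantification", counts = stage_counts$loop_quantification)))
  manifest <- write_manifest(manifest, outdir)
  hash <- manifest$manifest_hash

  paths <- character(0)
  for (nm in names(normed)) {
    pth <- file.path(outdir, paste0("observed_", nm, ".tsv"))
    write_contact_matrix(normed[[nm]], pth, header = paste0("manifest: ", hash))
    paths <- c(paths, pth)
    idx <- cm_upper_pairs(normed[[nm]])
    sm <- scored[[nm]]$scores
    px <- data.frame(bin_i = idx[, 1L], bin_j = idx[, 2L],
                     obs = normed[[nm]]$values[idx],
                     exp = scored[[nm]]$expected$values[idx],
                     ratio = sm$ratio[idx], p = sm$p_value[idx],
                     score = sm$score[idx])
    pth <- file.path(outdir, paste0("scores_", nm, ".tsv"))
    write_tsv_with_hash(format(px, digits = 12, scientific = TRUE), pth, hash)
    paths <- c(paths, pth)
  }
  biases <- do.call(rbind, lapply(names(iced), function(nm)
    data.frame(matrix = nm, row = seq_along(iced[[nm]]$biases),
               bias = iced[[nm]]$biases)))
  pth <- file.path(outdir, "ice_biases.tsv")
  write_tsv_with_hash(format(biases, digits = 12), pth, hash)
  paths <- c(paths, pth)
  if (!is.null(quant)) {
    pth <- file.path(outdir, "loop_quantification.tsv")
    write_tsv_with_hash(format(quant, digits = 12), pth, hash)
    paths <- c(paths, pth)
  }
  invisible(list(scores = scored, condition_matrices = cond_mats,
                 loop_quantification = quant, manifest = manifest,
                 paths = c(file.path(outdir, "manifest.json"), paths)))
}

#' Run the loop-span versus dysregulation analysis end-to-end
#'
#' Generates (or loads) the gene/loop/peak/enhancer fixture, classifies
#' loops and genes, computes per-gene longest and mean loop spans under the
#' all/CTCF/enhancer-promoter filters, and runs the class-pair
#' Kolmogorov-Smirnov comparisons and the promoter peak-binding Fisher
#' enrichment.
#'
#' @param config configuration list or YAML path (see the packaged
#'   `loopspan_config.yaml`). Either a `fixture` block (generator
#'   parameters) or an `inputs` block (paths to BED/BEDPE/gene tables and id
#'   lists) must be present.
#' @param outdir output directory.
#' @param seed optional override of the fixture seed.
#' @return invisibly, a list with the span tables, class assignments, KS
#'   statistics, enrichment results and manifest.
#' @export
run_loopspan_analysis <- function(config, outdir, seed = NULL) {
  config <- load_config(config)
  pars <- config$parameters
  if (is.null(pars)) pars <- list()
  alpha <- if (!is.null(pars$alpha)) pars$alpha else 0.05
  induction_lfc <- if (!is.null(pars$induction_lfc)) pars$induction_lfc else 1
  promoter_halfwidth <- if (!is.null(pars$promoter_halfwidth)) pars$promoter_halfwidth else 2000
  genotype_contrasts <- unlist(if (!is.null(pars$genotype_contrasts)) pars$genotype_contrasts
                               else c("nex_ttx", "nex_kcl6"))
  induction_contrasts <- unlist(if (!is.null(pars$induction_contrasts)) pars$induction_contrasts
                                else c("kcl1_vs_ttx", "kcl6_vs_ttx"))

  if (!is.null(config$fixture)) {
    fargs <- config$fixture
    if (!is.null(fargs$span_median)) fargs$span_median <- unlist(fargs$span_median)
    fargs$genotype_contrasts <- genotype_contrasts
    fargs$induction_contrasts <- induction_contrasts
    if (!is.null(seed)) fargs$seed <- seed
    fix <- simulate_gene_loop_fixture(do.call(gene_loop_config, fargs))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    fix <- list(genes = read_gene_table(inp$genes),
                loops = read_bedpe(inp$loops),
                peaks = read_bed(inp$ctcf_peaks),
                enhancers = read_bed(inp$enhancers),
                ieg = readLines(inp$ieg_list),
                lrg = readLines(inp$lrg_list))
  } else {
    ls_stop("config needs a 'fixture' or 'inputs' block", "loopscore_config_error")
  }

  classes <- assign_expression_class(fix$genes, fix$ieg, fix$lrg,
                                     genotype_contrasts = genotype_contrasts,
                                     induction_contrasts = induction_contrasts,
                                     alpha = alpha, induction_lfc = induction_lfc)
  cls <- classes$expression_class[match(fix$genes$gene_id, classes$gene_id)]
  # constitutive neuronal gene sets may loop to constitutive or inducible
  # enhancers; activity-regulated classes require inducible enhancers
  req_ind <- !(cls %in% c("constitutive", "inducible", "other"))
  gl <- gene_loop_table(fix$genes, fix$loops, fix$peaks, fix$enhancers,
                        require_inducible = req_ind)

  span_tabs <- list()
  for (filter in c("all", "ctcf", "enhancer_promoter")) {
    for (stat in c("longest", "mean")) {
      st <- loop_span_per_gene(fix$genes, gl, filter = filter, stat = stat)
      st$filter <- rep(filter, nrow(st))
      st$stat <- rep(stat, nrow(st))
      st$expression_class <- cls[match(st$gene_id, fix$genes$gene_id)]
      span_tabs[[paste(filter, stat, sep = ".")]] <- st
    }
  }
  spans <- do.call(rbind, span_tabs)
  rownames(spans) <- NULL

  class_pairs <- list(c("IEG", "downregulated_LRG"),
                      c("IEG", "non_deregulated_LRG"),
                      c("downregulated_LRG", "non_deregulated_LRG"))
  ks_rows <- list()
  for (key in names(span_tabs)) {
    st <- span_tabs[[key]]
    key_parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    for (cp in class_pairs) {
      a <- st$span[st$expression_class == cp[1L]]
      b <- st$span[st$expression_class == cp[2L]]
      if (length(a) >= 1L && length(b) >= 1L) {
        kt <- ks_two_sample(a, b)
        row <- data.frame(filter = key_parts[1L], stat = key_parts[2L],
                          class_a = cp[1L], class_b = cp[2L],
                          n_a = length(a), n_b = length(b),
                          median_a = stats::median(a), median_b = stats::median(b),
                          D = kt$D, p = kt$p, status = "ok")
      } else {
        row <- data.frame(filter = key_parts[1L], stat = key_parts[2L],
                          class_a = cp[1L], class_b = cp[2L],
                          n_a = length(a), n_b = length(b),
                          median_a = NA_real_, median_b = NA_real_,
                          D = NA_real_, p = NA_real_, status = "not computable")
      }
      ks_rows[[length(ks_rows) + 1L]] <- row
    }
  }
  ks_stats <- do.call(rbind, ks_rows)

  interest <- fix$genes[cls %in% c("IEG", "downregulated_LRG", "non_deregulated_LRG"), ,
                        drop = FALSE]
  background <- fix$genes[cls == "constitutive", , drop = FALSE]
  enrich <- if (nrow(interest) > 0L && nrow(background) > 0L) {
    tryCatch(promoter_binding_enrichment(interest, background, fix$peaks,
                                         promoter_halfwidth = promoter_halfwidth),
             loopscore_error = function(e) NULL)
  } else {
    NULL
  }

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    pipeline = "loop_span_analysis",
    package_version = as.character(utils::packageVersion("loopscore")),
    seed = if (!is.null(config$fixture)) {
      if (!is.null(seed)) seed else config$fixture$seed
    } else {
      NA
    },
    parameters = list(alpha = alpha, induction_lfc = induction_lfc,
                      promoter_halfwidth = promoter_halfwidth,
                      genotype_contrasts = genotype_contrasts,
                      induction_contrasts = induction_contrasts),
    counts = list(n_genes = nrow(fix$genes), n_loops = nrow(fix$loops),
                  n_peaks = nrow(fix$peaks), n_enhancers = nrow(fix$enhancers),
                  classes = as.list(table(cls))))
  manifest <- write_manifest(manifest, outdir)
  hash <- manifest$manifest_hash
  write_tsv_with_hash(format(spans, digits = 10), file.path(outdir, "gene_spans.tsv"), hash)
  write_tsv_with_hash(classes, file.path(outdir, "class_assignments.tsv"), hash)
  write_tsv_with_hash(format(ks_stats, digits = 10), file.path(outdir, "ks_stats.tsv"), hash)
  if (!is.null(enrich)) {
    enr_df <- data.frame(comparison = "ARG_vs_constitutive_promoter_peaks",
                         bound_interest = enrich$table[1L, 1L],
                         bound_background = enrich$table[1L, 2L],
                         unbound_interest = enrich$table[2L, 1L],
                         unbound_background = enrich$table[2L, 2L],
                         odds_ratio = enrich$odds_ratio, p = enrich$p)
    write_tsv_with_hash(format(enr_df, digits = 10),
                        file.path(outdir, "promoter_enrichment.tsv"), hash)
  }
  invisible(list(spans = spans, classes = classes, ks_stats = ks_stats,
                 enrichment = enrich, gene_loops = gl, fixture = fix,
                 manifest = manifest))
}
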