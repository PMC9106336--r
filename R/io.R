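# Readers/writers for the plain-text annotation formats the analysis consumes:
# BED3+ for peaks/enhancers, BEDPE for loops, TSV for gene records.

split_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a BED file of peaks or enhancers
#'
#' BED3+ with 0-based half-open coordinates. Column 4 (if present) is kept as
#' the peak-set `label`; column 7 (if present) is parsed as a logical
#' `inducible` flag for enhancer files (accepts TRUE/FALSE, 1/0,
#' inducible/constitutive).
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `inducible`; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  fields <- split_tsv_lines(path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      label = character(), inducible = logical(),
                      stringsAsFactors = FALSE)
  if (length(fields) == 0L) return(empty)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      ls_stop(sprintf("BED parse error at line %d: %d column(s), need >= 3", i, length(f)),
              "loopscore_parse_error")
    }
    if (is.na(suppressWarnings(as.numeric(f[2L]))) ||
        is.na(suppressWarnings(as.numeric(f[3L])))) {
      ls_stop(sprintf("BED parse error at line %d: non-numeric coordinates", i),
              "loopscore_parse_error")
    }
  }
  chrom <- vapply(fields, `[`, character(1L), 1L)
  start <- as.numeric(vapply(fields, `[`, character(1L), 2L))
  end <- as.numeric(vapply(fields, `[`, character(1L), 3L))
  label <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_,
                  character(1L))
  ind_raw <- vapply(fields, function(f) if (length(f) >= 7L) f[7L] else NA_character_,
                    character(1L))
  inducible <- tolower(ind_raw) %in% c("true", "1", "inducible")
  inducible[is.na(ind_raw)] <- NA
  df <- data.frame(chrom = chrom, start = start, end = end, label = label,
                   inducible = inducible, stringsAsFactors = FALSE)
  bad <- which(!(df$end > df$start) | df$start < 0)
  if (length(bad) > 0L) {
    ls_stop(sprintf("BED validation error at line %d: end <= start", bad[1L]),
            "loopscore_validation_error")
  }
  df
}

#' Write peaks/enhancers as BED
#'
#' @param x data.frame as returned by [read_bed()].
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  cols <- data.frame(chrom = x$chrom,
                     start = format(x$start, scientific = FALSE, trim = TRUE),
                     end = format(x$end, scientific = FALSE, trim = TRUE))
  has_label <- !is.null(x$label) && any(!is.na(x$label))
  has_ind <- !is.null(x$inducible) && any(!is.na(x$inducible))
  if (has_label || has_ind) cols$label <- ifelse(is.na(x$label), ".", x$label)
  if (has_ind) {
    cols$score <- "0"
    cols$strand <- "."
    cols$inducible <- ifelse(x$inducible, "TRUE", "FALSE")
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of chromatin loops
#'
#' Requires >= 6 columns. Anchors are reordered so that anchor 1 is the
#' upstream one; trans (different-chromosome) entries are excluded with a
#' warning, and their count is attached as attribute `n_trans`.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `name`.
#' @export
read_bedpe <- function(path) {
  fields <- split_tsv_lines(path)
  empty <- data.frame(chrom = character(), start1 = numeric(), end1 = numeric(),
                      start2 = numeric(), end2 = numeric(), name = character(),
                      stringsAsFactors = FALSE)
  if (length(fields) == 0L) {
    attr(empty, "n_trans") <- 0L
    return(empty)
  }
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 6L) {
      ls_stop(sprintf("BEDPE parse error at line %d: %d column(s), need >= 6",
                      i, length(fields[[i]])), "loopscore_parse_error")
    }
  }
  g <- function(k) vapply(fields, `[`, character(1L), k)
  chrom1 <- g(1L); chrom2 <- g(4L)
  s1 <- as.numeric(g(2L)); e1 <- as.numeric(g(3L))
  s2 <- as.numeric(g(5L)); e2 <- as.numeric(g(6L))
  name <- vapply(fields, function(f) if (length(f) >= 7L) f[7L] else NA_character_,
                 character(1L))
  trans <- chrom1 != chrom2
  if (any(trans)) {
    warning(sprintf("read_bedpe: excluded %d trans entr%s", sum(trans),
                    if (sum(trans) == 1L) "y" else "ies"))
  }
  keep <- !trans
  chrom1 <- chrom1[keep]; name <- name[keep]
  s1 <- s1[keep]; e1 <- e1[keep]; s2 <- s2[keep]; e2 <- e2[keep]
  # order anchors along the genome
  swap <- s2 < s1
  tmp_s <- s1[swap]; tmp_e <- e1[swap]
  s1[swap] <- s2[swap]; e1[swap] <- e2[swap]
  s2[swap] <- tmp_s; e2[swap] <- tmp_e
  df <- data.frame(chrom = chrom1, start1 = s1, end1 = e1,
                   start2 = s2, end2 = e2, name = name, stringsAsFactors = FALSE)
  validate_intervals(data.frame(chrom = df$chrom, start = df$start1, end = df$end1),
                     "BEDPE anchor 1")
  validate_intervals(data.frame(chrom = df$chrom, start = df$start2, end = df$end2),
                     "BEDPE anchor 2")
  attr(df, "n_trans") <- sum(trans)
  df
}

#' Write loops as BEDPE
#'
#' @param x loop table as returned by [read_bedpe()].
#' @param path output file.
#' @export
write_bedpe <- function(x, path) {
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  out <- data.frame(x$chrom, fmt(x$start1), fmt(x$end1),
                    x$chrom, fmt(x$start2), fmt(x$end2),
                    if (!is.null(x$name)) ifelse(is.na(x$name), ".", x$name) else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write the gene record table
#'
#' TSV with header: `gene_id`, `chrom`, `tss`, `class_label`, then per-contrast
#' columns `log2fc_<contrast>`, `padj_<contrast>`, `expressed_<contrast>`.
#' The TSS is a 0-based base position (a width-1 interval).
#'
#' @param path file path.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    ls_stop(paste0("gene table missing column(s): ", paste(miss, collapse = ", ")),
            "loopscore_parse_error")
  }
  pad <- grep("^padj_", names(df), value = TRUE)
  for (p in pad) {
    bad <- !is.na(df[[p]]) & (df[[p]] < 0 | df[[p]] > 1)
    if (any(bad)) {
      ls_stop(sprintf("gene table: %s outside [0,1] at row %d", p, which(bad)[1L]),
              "loopscore_validation_error")
    }
  }
  df
}

#' @rdname read_gene_table
#' @param x gene table.
#' @export
write_gene_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
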