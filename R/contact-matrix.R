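# The contact_matrix container: a symmetric square matrix of non-negative
# values over a coordinate axis (primer, fragment or bin intervals), plus a
# symmetric informative-pixel mask. Non-informative entries carry NA.

#' Construct a contact matrix
#'
#' @param values symmetric square numeric matrix; entries outside
#'   `informative` are set to `NA`.
#' @param informative symmetric logical matrix of the same dimension marking
#'   pixels that are queryable and not removed. Defaults to all non-`NA`
#'   entries of `values`.
#' @param axis data.frame with one row per matrix row: `chrom`, `start`,
#'   `end` of the primer/fragment/bin interval.
#' @param level one of `"primer"`, `"fragment"`, `"bin"`.
#' @return an object of class `contact_matrix` (a list with elements
#'   `values`, `informative`, `axis`, `level`).
#' @export
contact_matrix <- function(values, informative = NULL, axis, level = c("primer", "fragment", "bin")) {
  level <- match.arg(level)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(informative)) informative <- !is.na(values)
  stopifnot(is.matrix(informative), dim(informative) == dim(values))
  if (!identical(informative, t(informative))) {
    ls_stop("informative mask is not symmetric", "loopscore_validation_error")
  }
  if (nrow(axis) != nrow(values)) {
    ls_stop("axis has wrong number of rows", "loopscore_validation_error")
  }
  validate_intervals(axis, paste(level, "axis"))
  v <- values
  v[!informative] <- NA_real_
  vi <- v[informative]
  if (length(vi) > 0L) {
    if (any(is.na(vi))) {
      ls_stop("NA value on an informative pixel", "loopscore_validation_error")
    }
    if (any(vi < 0)) {
      ls_stop("negative value on an informative pixel", "loopscore_validation_error")
    }
    if (max(abs(v - t(v)), na.rm = TRUE) > 1e-9 * max(1, max(abs(vi)))) {
      ls_stop("contact matrix values are not symmetric", "loopscore_validation_error")
    }
  }
  structure(list(values = v, informative = informative,
                 axis = as.data.frame(axis), level = level),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d at %s level; %d informative pixels; %s:%s-%s\n",
              nrow(x$values), ncol(x$values), x$level, sum(x$informative),
              x$axis$chrom[1L], format(min(x$axis$start), scientific = FALSE),
              format(max(x$axis$end), scientific = FALSE)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

# Upper-triangle (i < j) informative index pairs, as a 2-column matrix.
cm_upper_pairs <- function(cm) {
  idx <- which(cm$informative & upper.tri(cm$informative), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

#' Write / read a contact matrix as sparse TSV triplets
#'
#' The triplet file holds the informative upper triangle (`bin_i`, `bin_j`,
#' `value`, 1-based indices); the axis table accompanies it.
#'
#' @param cm a `contact_matrix`.
#' @param path triplet file path; the axis table goes to `<path>.axis`.
#' @param header optional comment line (without the leading `#`).
#' @export
write_contact_matrix <- function(cm, path, header = NULL) {
  idx <- cm_upper_pairs(cm)
  trip <- data.frame(bin_i = idx[, 1L], bin_j = idx[, 2L],
                     value = cm$values[idx])
  con <- file(path, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(trip, digits = 15, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ax <- cbind(cm$axis, level = cm$level)
  utils::write.table(ax, paste0(path, ".axis"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  trip <- utils::read.delim(path, comment.char = "#")
  ax <- utils::read.delim(paste0(path, ".axis"), stringsAsFactors = FALSE)
  n <- nrow(ax)
  v <- matrix(NA_real_, n, n)
  inf <- matrix(FALSE, n, n)
  ij <- cbind(trip$bin_i, trip$bin_j)
  v[ij] <- trip$value
  v[ij[, c(2L, 1L), drop = FALSE]] <- trip$value
  inf[ij] <- TRUE
  inf[ij[, c(2L, 1L), drop = FALSE]] <- TRUE
  contact_matrix(v, inf, ax[, c("chrom", "start", "end")], level = ax$level[1L])
}
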