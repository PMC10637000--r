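#' Write a susceptibility matrix to disk
#'
#' `format = "tsv"` writes a dense table (gene rows, subfamily columns) plus
#' a sidecar `<path>.meta.tsv` with the build metadata (mode, bandwidth or
#' flank, TAD restriction). `format = "mtx"` writes a MatrixMarket sparse
#' file with `<path>.rows` / `<path>.cols` label files and the same sidecar.
#'
#' @param N A `susceptibility_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return Invisibly, `path`.
#' @export
write_susceptibility <- function(N, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(N, "susceptibility_matrix"))
  meta <- tibble::tibble(
    key = c("mode", "bandwidth", "flank", "tad_restricted"),
    value = c(N$mode,
              if (is.null(N$bandwidth)) "" else format(N$bandwidth),
              if (is.null(N$flank)) "" else format(N$flank),
              as.character(isTRUE(N$tad_restricted)))
  )
  readr::write_tsv(meta, paste0(path, ".meta.tsv"))
  if (format == "tsv") {
    df <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(N$values)),
                           tibble::as_tibble(N$values))
    readr::write_tsv(df, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(N$values, sparse = TRUE), path)
    writeLines(rownames(N$values), paste0(path, ".rows"))
    writeLines(colnames(N$values), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read a susceptibility matrix written by [write_susceptibility()]
#'
#' @param path Path given to the writer.
#' @param format `"tsv"` or `"mtx"`.
#' @return A `susceptibility_matrix`.
#' @export
read_susceptibility <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  meta_path <- paste0(path, ".meta.tsv")
  meta <- if (file.exists(meta_path)) {
    m <- readr::read_tsv(meta_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
    stats::setNames(m$value, m$key)
  } else c(mode = "hard", bandwidth = "", flank = "", tad_restricted = "FALSE")
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    values <- as.matrix(df[, -1, drop = FALSE])
    rownames(values) <- df$gene_id
  } else {
    values <- as.matrix(Matrix::readMM(path))
    rownames(values) <- readLines(paste0(path, ".rows"))
    colnames(values) <- readLines(paste0(path, ".cols"))
  }
  new_susceptibility_matrix(
    values, meta[["mode"]],
    bandwidth = if (nzchar(meta[["bandwidth"]])) as.numeric(meta[["bandwidth"]]) else NULL,
    flank = if (nzchar(meta[["flank"]])) as.numeric(meta[["flank"]]) else NULL,
    tad_restricted = identical(meta[["tad_restricted"]], "TRUE")
  )
}

#' Write an activity table to TSV
#'
#' Per-subfamily rows use the conventional linear-model column names
#' (`Estimate`, `Std. Error`, `t value`, `Pr(>|t|)`, `p_adj`), preceded by a
#' commented header block carrying the intercept, overall F-test p-value,
#' adjusted R-squared, observation count and residual degrees of freedom.
#'
#' @param fit A `te_activity_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_activity_table <- function(fit, path) {
  stopifnot(inherits(fit, "te_activity_fit"))
  hdr <- c(
    sprintf("# intercept\t%.10g", fit$intercept),
    sprintf("# f_p_value\t%.10g", fit$f_p_value),
    sprintf("# adj_r_squared\t%.10g", fit$adj_r_squared),
    sprintf("# n_obs\t%d", fit$n_obs),
    sprintf("# residual_df\t%d", fit$residual_df)
  )
  tab <- fit$table
  out <- tibble::tibble(
    subfamily = tab$subfamily,
    `Estimate` = tab$estimate,
    `Std. Error` = tab$std_error,
    `t value` = tab$t_value,
    `Pr(>|t|)` = tab$p_value,
    p_adj = tab$adj_p_value
  )
  writeLines(hdr, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read TAD or functional intervals from a BED3+ file
#'
#' @param path Path to a BED file (first three columns used).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3)) {
    bad <- which(lengths(fields) < 3)[1]
    te_abort(sprintf("malformed BED record at line %d", bad), "te_parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  tibble::tibble(chrom = m[, 1], start = as.numeric(m[, 2]),
                 end = as.numeric(m[, 3]))
}
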