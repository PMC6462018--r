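#' Expression matrix with a units tag
#'
#' A thin wrapper around a numeric genes x samples matrix carrying a `units`
#' attribute, one of `"FPKM"`, `"TPM"` or `"LOG2TPM1"`. Gene and sample
#' identifiers are the dimnames and must be unique; all entries must be finite,
#' and non-negative when the units are FPKM or TPM.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param units one of `"FPKM"`, `"TPM"`, `"LOG2TPM1"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, units = c("FPKM", "TPM", "LOG2TPM1")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) && nrow(values) == 0) gid <- rownames(values) <- character(0)
  if (is.null(sid) && ncol(values) == 0) sid <- colnames(values) <- character(0)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value for gene '%s', sample '%s'",
                 gid[bad[1]], sid[bad[2]]))
  }
  if (units %in% c("FPKM", "TPM") && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value for gene '%s', sample '%s' (units %s)",
                 gid[bad[1]], sid[bad[2]], units))
  }
  structure(values, units = units, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, units = %s\n",
              nrow(x), ncol(x), expr_units(x)))
  invisible(x)
}

#' Units tag of an expression matrix
#' @param m an [expr_matrix()].
#' @return `"FPKM"`, `"TPM"` or `"LOG2TPM1"`.
#' @export
expr_units <- function(m) attr(m, "units")

#' Drop the expression-matrix wrapper
#' @param x an [expr_matrix()].
#' @param ... unused.
#' @return The bare numeric matrix (dimnames kept, units tag dropped).
#' @export
as.matrix.expr_matrix <- function(x, ...) {
  attr(x, "units") <- NULL
  class(x) <- NULL
  x
}

.assert_units <- function(m, expected) {
  if (!inherits(m, "expr_matrix")) stop("expected an expr_matrix")
  if (!expr_units(m) %in% expected)
    stop(sprintf("expected units %s, got %s",
                 paste(expected, collapse = " or "), expr_units(m)))
  invisible(m)
}

#' Read a gene x sample expression table
#'
#' Reads a UTF-8 tab-separated table whose first column (header `gene_id`)
#' holds gene identifiers and remaining columns one sample each. Duplicate
#' gene or sample ids, blank cells, non-numeric or negative entries are
#' errors; row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @param units units tag of the stored values.
#' @return An [expr_matrix()].
#' @export
read_expression_table <- function(path, units = c("FPKM", "TPM", "LOG2TPM1")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = NULL,
                   fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("expression table needs a gene_id column plus >= 1 sample")
  gid <- df[[1]]
  sid <- colnames(df)[-1]
  if (anyDuplicated(gid))
    stop("duplicated gene id in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicated sample id in ", path, ": ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(sid),
                 dimnames = list(gid, sid))
  for (j in seq_along(sid)) {
    cell <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !nzchar(trimws(cell)))
    if (length(bad))
      stop(sprintf("non-numeric or blank entry for gene '%s', sample '%s'",
                   gid[bad[1]], sid[j]))
    neg <- which(num < 0)
    if (length(neg) && units %in% c("FPKM", "TPM"))
      stop(sprintf("negative value for gene '%s', sample '%s'",
                   gid[neg[1]], sid[j]))
    vals[, j] <- num
  }
  expr_matrix(vals, units)
}

#' Convert FPKM to TPM
#'
#' Rescales each sample so that its abundances sum to one million:
#' `TPM_ij = FPKM_ij / sum_i(FPKM_ij) * 1e6`. The conversion is performed over
#' the genes present in the matrix as loaded, before any gene filtering.
#'
#' @param m an [expr_matrix()] with units `"FPKM"`.
#' @return An [expr_matrix()] with units `"TPM"`; every column sums to 1e6.
#' @export
fpkm_to_tpm <- function(m) {
  .assert_units(m, "FPKM")
  cs <- colSums(m)
  if (any(cs == 0))
    stop("sample(s) with all-zero expression: ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  out <- sweep(unclass(m), 2, cs, "/") * 1e6
  expr_matrix(out, "TPM")
}

#' log2(TPM + 1) transform
#'
#' Applies `log2(x + 1)` entrywise to shrink the numeric range; zeros map to
#' zeros and the transform is strictly monotone (invertible via `2^x - 1`).
#'
#' @param m an [expr_matrix()] with units `"TPM"`.
#' @return An [expr_matrix()] with units `"LOG2TPM1"`.
#' @export
log2p1_transform <- function(m) {
  .assert_units(m, "TPM")
  expr_matrix(log2(unclass(m) + 1), "LOG2TPM1")
}
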