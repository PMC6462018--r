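#' Read a sample sheet
#'
#' Reads a tab-separated sheet with columns `sample_id`, `patient_id` and
#' `tissue` (`tumour`/`tumor` or `normal`, case-insensitive). Within a sheet a
#' patient may have at most one sample per tissue.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id`, `patient_id`, `tissue`
#'   (`"TUMOUR"` / `"NORMAL"`).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   fileEncoding = "UTF-8")
  need <- c("sample_id", "patient_id", "tissue")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  as_sample_sheet(df[need])
}

#' Validate a sample sheet data frame
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `tissue`.
#' @return The normalised sheet (tissue upper-cased to `TUMOUR`/`NORMAL`).
#' @export
as_sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  tis <- toupper(trimws(df$tissue))
  tis[tis == "TUMOR"] <- "TUMOUR"
  if (!all(tis %in% c("TUMOUR", "NORMAL")))
    stop("tissue must be 'tumour' or 'normal' (got: ",
         paste(unique(df$tissue[!tis %in% c("TUMOUR", "NORMAL")]), collapse = ", "), ")")
  df$tissue <- tis
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  key <- paste(df$patient_id, df$tissue)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, tissue) pair in sample sheet: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df
}

#' Assemble a matched tumour/normal cohort
#'
#' Keeps only patients that contribute both a tumour and a normal sample,
#' aligns the two sub-matrices column-by-column on patient id, and reports
#' the patients dropped for lacking one tissue.
#'
#' @param m an [expr_matrix()] containing all samples.
#' @param sheet a sample sheet (data.frame as from [read_sample_sheet()]).
#' @return An object of class `paired_cohort`: a list with elements `tumour`
#'   and `normal` (each an [expr_matrix()] with identical gene order),
#'   `patient_ids` (column order of both), and `dropped_patients`.
#' @export
build_paired_cohort <- function(m, sheet) {
  if (!inherits(m, "expr_matrix")) stop("`m` must be an expr_matrix")
  sheet <- as_sample_sheet(sheet)
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing))
    stop("sample(s) in expression matrix absent from sample sheet: ",
         paste(missing, collapse = ", "))
  sheet <- sheet[sheet$sample_id %in% colnames(m), , drop = FALSE]
  tum <- sheet[sheet$tissue == "TUMOUR", ]
  nor <- sheet[sheet$tissue == "NORMAL", ]
  complete <- intersect(tum$patient_id, nor$patient_id)
  # preserve the matrix's tumour-sample order for patient ordering
  tum_order <- tum$patient_id[order(match(tum$sample_id, colnames(m)))]
  patients <- tum_order[tum_order %in% complete]
  dropped <- setdiff(unique(sheet$patient_id), complete)
  if (!length(patients))
    stop("no patient has both a tumour and a normal sample")
  ts <- tum$sample_id[match(patients, tum$patient_id)]
  ns <- nor$sample_id[match(patients, nor$patient_id)]
  u <- expr_units(m)
  mk <- function(samples) {
    sub <- unclass(m)[, samples, drop = FALSE]
    colnames(sub) <- samples
    expr_matrix(sub, u)
  }
  structure(list(tumour = mk(ts), normal = mk(ns),
                 patient_ids = patients, dropped_patients = dropped),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d genes, %d matched tumour/normal pairs (units %s)\n",
              nrow(x$tumour), length(x$patient_ids), expr_units(x$tumour)))
  if (length(x$dropped_patients))
    cat("  dropped (one tissue only):", length(x$dropped_patients), "patient(s)\n")
  invisible(x)
}

#' Number of genes / pairs in a paired cohort
#' @param x a `paired_cohort`.
#' @export
dim.paired_cohort <- function(x) c(nrow(x$tumour), length(x$patient_ids))

#' Remove zero-heavy genes from a paired cohort
#'
#' A gene is removed when its fraction of exact zeros strictly exceeds
#' `max_zero_fraction` in the tumour sub-matrix or in the normal sub-matrix
#' (evaluated separately per tissue, since zero-heavy genes destabilise the
#' per-tissue mixture fits). Gene order is preserved among survivors.
#'
#' @param cohort a `paired_cohort` (values on the TPM or log2(TPM+1) scale).
#' @param max_zero_fraction genes with a zero fraction strictly above this in
#'   either tissue are removed; default 0.20.
#' @return list with `cohort` (filtered `paired_cohort`) and
#'   `removed_gene_ids` (character vector, for audit).
#' @export
filter_by_zero_fraction <- function(cohort, max_zero_fraction = 0.20) {
  if (!inherits(cohort, "paired_cohort")) stop("`cohort` must be a paired_cohort")
  if (!nrow(cohort$tumour)) stop("empty cohort")
  if (max_zero_fraction < 0 || max_zero_fraction >= 1)
    stop("`max_zero_fraction` must be in [0, 1)")
  zf_t <- rowMeans(unclass(cohort$tumour) == 0)
  zf_n <- rowMeans(unclass(cohort$normal) == 0)
  drop <- zf_t > max_zero_fraction | zf_n > max_zero_fraction
  removed <- rownames(cohort$tumour)[drop]
  u <- expr_units(cohort$tumour)
  keep1 <- function(m) expr_matrix(unclass(m)[!drop, , drop = FALSE], u)
  out <- structure(list(tumour = keep1(cohort$tumour),
                        normal = keep1(cohort$normal),
                        patient_ids = cohort$patient_ids,
                        dropped_patients = cohort$dropped_patients),
                   class = "paired_cohort")
  list(cohort = out, removed_gene_ids = removed)
}
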