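#' Scan a paired cohort for oncogene candidates
#'
#' Runs the per-gene discovery pipeline on a filtered, log2(TPM+1)-scale
#' paired cohort: fits the two-component equal-variance mixture to every
#' gene's tumour and normal values independently, computes the tumour
#' low/high boundary, the selectivity index (fraction of normal samples below
#' the tumour boundary), the oncogene-likeness score, and the size of the
#' overexpressing tumour subgroup; then ranks gate-passing genes.
#'
#' Per-gene seeds are derived from `master_seed` plus the gene index, so a
#' scan is exactly reproducible and insensitive to chunking.
#'
#' @param cohort a `paired_cohort` (units `LOG2TPM1` recommended).
#' @param master_seed integer master seed for the EM restarts.
#' @param si_threshold strict selectivity gate; default 0.99.
#' @param top_n candidates to report; default 5.
#' @param drop_nonconverged if `TRUE` (default) genes whose tumour or normal
#'   fit failed to converge are ineligible for ranking.
#' @param restarts,tol,max_iter,sigma_floor EM settings, see [gmm2()].
#' @return An object of class `oc_scan`: list with `summaries` (per-gene
#'   data.frame), `fits` (long per-tissue fit table), `ranked`, `top`,
#'   `n_pairs`, `params`.
#' @export
oc_scan <- function(cohort, master_seed = 1L, si_threshold = 0.99, top_n = 5,
                    drop_nonconverged = TRUE, restarts = 5L, tol = 1e-8,
                    max_iter = 5000L, sigma_floor = 1e-6) {
  if (!inherits(cohort, "paired_cohort")) stop("`cohort` must be a paired_cohort")
  XT <- unclass(cohort$tumour); XN <- unclass(cohort$normal)
  g <- nrow(XT)
  if (!g) stop("empty cohort")
  ms <- as.numeric(master_seed)
  ft <- .fit_rows(XT, ms + seq_len(g), restarts, tol, max_iter, sigma_floor)
  fn <- .fit_rows(XN, ms + g + seq_len(g), restarts, tol, max_iter, sigma_floor)

  si <- rep(NA_real_, g)
  ok_b <- !is.na(ft$boundary)
  si[ok_b] <- rowMeans(XN[ok_b, , drop = FALSE] < ft$boundary[ok_b])
  n_high <- rep(NA_integer_, g)
  n_high[ok_b] <- rowSums(XT[ok_b, , drop = FALSE] >= ft$boundary[ok_b])

  conv <- if (drop_nonconverged) ft$converged & fn$converged else
    !is.na(ft$log_lik) & !is.na(fn$log_lik)
  eligible <- conv & ok_b & !is.na(si)
  score <- .score_num(ft$mu_low, ft$mu_high, ft$sigma,
                      fn$mu_low, fn$mu_high, fn$sigma)
  score[!conv] <- NA_real_

  summaries <- data.frame(
    gene_id = rownames(XT),
    si = si,
    pi_T = ft$pi, mu_TL = ft$mu_low, mu_TH = ft$mu_high, sigma_T = ft$sigma,
    pi_N = fn$pi, mu_NL = fn$mu_low, mu_NH = fn$mu_high, sigma_N = fn$sigma,
    delta_high = ft$mu_high - fn$mu_high,
    delta_low = ft$mu_low - fn$mu_low,
    boundary_T = ft$boundary,
    n_tumour_high = n_high,
    score = score,
    eligible = eligible,
    stringsAsFactors = FALSE
  )
  fits <- rbind(
    data.frame(gene_id = rownames(XT), tissue = "TUMOUR", ft,
               stringsAsFactors = FALSE),
    data.frame(gene_id = rownames(XN), tissue = "NORMAL", fn,
               stringsAsFactors = FALSE)
  )
  rk <- rank_candidates(summaries, si_threshold, top_n)
  structure(list(summaries = summaries, fits = fits, ranked = rk$ranked,
                 top = rk$top, n_pairs = length(cohort$patient_ids),
                 params = list(master_seed = as.integer(master_seed),
                               si_threshold = si_threshold, top_n = top_n,
                               drop_nonconverged = drop_nonconverged,
                               restarts = restarts, tol = tol,
                               max_iter = max_iter, sigma_floor = sigma_floor)),
            class = "oc_scan")
}

#' @export
print.oc_scan <- function(x, ...) {
  cat(sprintf("<oc_scan> %d genes over %d tumour/normal pairs\n",
              nrow(x$summaries), x$n_pairs))
  cat(sprintf("  eligible fits: %d;  passing si > %.2f: %d\n",
              sum(x$summaries$eligible), x$params$si_threshold, nrow(x$ranked)))
  if (nrow(x$top)) {
    cat("  top candidates:\n")
    print(x$top[, c("gene_id", "si", "score", "n_tumour_high")], row.names = FALSE)
  } else cat("  no gene passed the selectivity gate\n")
  invisible(x)
}

#' @export
summary.oc_scan <- function(object, ...) {
  s <- object$summaries
  out <- list(
    n_genes = nrow(s),
    n_pairs = object$n_pairs,
    n_converged_both = sum(s$eligible),
    n_gate = nrow(object$ranked),
    si_quartiles = quantile(s$si, c(0.25, 0.5, 0.75), na.rm = TRUE),
    score_quartiles = quantile(s$score, c(0.25, 0.5, 0.75), na.rm = TRUE),
    top = object$top
  )
  class(out) <- "summary.oc_scan"
  out
}

#' @export
print.summary.oc_scan <- function(x, ...) {
  cat(sprintf("oc_scan of %d genes x %d pairs: %d eligible, %d pass the gate\n",
              x$n_genes, x$n_pairs, x$n_converged_both, x$n_gate))
  cat("selectivity index quartiles:",
      paste(formatC(x$si_quartiles, digits = 3, format = "f"), collapse = " / "), "\n")
  cat("score quartiles:",
      paste(formatC(x$score_quartiles, digits = 3, format = "f"), collapse = " / "), "\n")
  if (nrow(x$top)) print(x$top[, c("gene_id", "si", "score")], row.names = FALSE)
  invisible(x)
}

#' Tumour vs normal histograms for one scanned gene
#'
#' @param x an `oc_scan`.
#' @param cohort the `paired_cohort` the scan was run on.
#' @param gene_id gene to display; defaults to the top candidate.
#' @param ... passed to [graphics::hist()].
#' @export
plot.oc_scan <- function(x, cohort, gene_id = NULL, ...) {
  if (is.null(gene_id)) {
    if (!nrow(x$top)) stop("no candidate to plot; supply `gene_id`")
    gene_id <- x$top$gene_id[1]
  }
  xt <- unclass(cohort$tumour)[gene_id, ]
  xn <- unclass(cohort$normal)[gene_id, ]
  brk <- seq(min(xt, xn), max(xt, xn), length.out = 25)
  ht <- graphics::hist(xt, breaks = brk, plot = FALSE)
  hn <- graphics::hist(xn, breaks = brk, plot = FALSE)
  ylim <- c(0, max(ht$density, hn$density))
  graphics::plot(ht, freq = FALSE, col = grDevices::adjustcolor("darkcyan", 0.5),
                 border = NA, ylim = ylim, main = gene_id,
                 xlab = "log2(TPM + 1)", ...)
  graphics::plot(hn, freq = FALSE, col = grDevices::adjustcolor("orange", 0.5),
                 border = NA, add = TRUE)
  b <- x$summaries$boundary_T[x$summaries$gene_id == gene_id]
  if (length(b) && !is.na(b)) graphics::abline(v = b, lty = 2)
  invisible(x)
}
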