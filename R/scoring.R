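#' Selectivity index
#'
#' Fraction of adjacent-normal samples whose expression lies strictly below
#' the tumour low/high boundary. An SI near 1 means essentially every normal
#' sample sits below the value at which tumours switch from baseline to
#' overexpressed, i.e. the gene is selectively overexpressed in tumours. A
#' normal value exactly equal to the boundary does not count as below.
#'
#' @param normal_values numeric vector of adjacent-normal expression values
#'   (non-empty, finite).
#' @param tumour_boundary the boundary from the tumour-tissue fit (finite).
#' @return A value in \[0, 1\].
#' @export
selectivity_index <- function(normal_values, tumour_boundary) {
  if (!length(normal_values)) stop("`normal_values` must be non-empty")
  if (!all(is.finite(normal_values))) stop("`normal_values` must be finite")
  if (!is.numeric(tumour_boundary) || length(tumour_boundary) != 1 ||
      !is.finite(tumour_boundary))
    stop("`tumour_boundary` must be a single finite number")
  mean(normal_values < tumour_boundary)
}

#' Oncogene-likeness score
#'
#' Scores a gene's similarity to the theoretical ideal oncogene candidate —
#' a large tumour-specific high mode over matched low baselines with tight
#' components:
#' \deqn{score = (\mu_{TH} - \mu_{NH}) - |\mu_{TL} - \mu_{NL}| -
#'   (\sigma_T + \sigma_N)}
#' Larger is more oncogene-like. The formula is deliberately isolated here so
#' an alternative parameterisation can be swapped in without touching the
#' gate or ranking logic.
#'
#' @param fit_t,fit_n [gmm2()] fits for tumour and normal tissue (ordered
#'   means). If either fit did not converge the score is undefined (`NA`).
#' @return The score, or `NA_real_` if either fit is non-converged.
#' @export
oncomix_score <- function(fit_t, fit_n) {
  if (!isTRUE(fit_t$converged) || !isTRUE(fit_n$converged)) return(NA_real_)
  .score_num(fit_t$mu_low, fit_t$mu_high, fit_t$sigma,
             fit_n$mu_low, fit_n$mu_high, fit_n$sigma)
}

.score_num <- function(mu_tl, mu_th, sigma_t, mu_nl, mu_nh, sigma_n) {
  (mu_th - mu_nh) - abs(mu_tl - mu_nl) - (sigma_t + sigma_n)
}

#' Rank oncogene candidates
#'
#' Applies the strict selectivity gate (`si > si_threshold`), drops ineligible
#' genes, sorts survivors by score (descending, ties broken lexicographically
#' by gene id), and returns the top of the list along with the full ranked
#' table.
#'
#' @param summaries data.frame of per-gene summaries as produced by
#'   [oc_scan()] (needs columns `gene_id`, `si`, `score`, `eligible`).
#' @param si_threshold strict lower gate on the selectivity index; default
#'   0.99 (a gene with SI exactly 0.99 fails).
#' @param top_n number of top genes to return; default 5.
#' @return list with `top` (first `top_n` rows) and `ranked` (all gate
#'   passers, sorted). If no gene passes, both are empty and a warning is
#'   raised.
#' @export
rank_candidates <- function(summaries, si_threshold = 0.99, top_n = 5) {
  if (!nrow(summaries)) stop("`summaries` must be non-empty")
  need <- c("gene_id", "si", "score", "eligible")
  if (!all(need %in% colnames(summaries)))
    stop("`summaries` needs columns: ", paste(need, collapse = ", "))
  keep <- !is.na(summaries$si) & summaries$si > si_threshold &
    summaries$eligible & !is.na(summaries$score)
  ranked <- summaries[keep, , drop = FALSE]
  if (!nrow(ranked)) {
    warning("no gene passes the selectivity gate (si > ", si_threshold, ")")
    return(list(top = ranked, ranked = ranked))
  }
  ord <- order(-ranked$score, ranked$gene_id)
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  list(top = head(ranked, top_n), ranked = ranked)
}

#' Theoretical ideal oncogene-candidate profile
#'
#' Generates the expression pattern of the ideal oncogene candidate used as a
#' positive control: adjacent normal unimodal at `mu_base`, tumours an even
#' mixture of a baseline component at `mu_base` and a clearly separated high
#' component at `mu_base + delta`, all with common standard deviation `sigma`
#' and clipped at zero.
#'
#' @param n_t,n_n number of tumour / normal samples (each >= 4).
#' @param seed integer seed (fixed seed gives identical output).
#' @param mu_base baseline mean; default 1.
#' @param delta separation of the tumour high mode; default 4.
#' @param sigma common component SD; default 0.2.
#' @param pi_t fraction of tumours in the high component; default 0.5.
#' @return list with numeric vectors `tumour` and `normal`.
#' @export
ideal_profile <- function(n_t, n_n, seed = 1L, mu_base = 1, delta = 4,
                          sigma = 0.2, pi_t = 0.5) {
  if (n_t < 4 || n_n < 4) stop("n_t and n_n must each be >= 4")
  set.seed(as.integer(seed))
  hi <- rbinom(n_t, 1, pi_t)
  tumour <- pmax(rnorm(n_t, mu_base + delta * hi, sigma), 0)
  normal <- pmax(rnorm(n_n, mu_base, sigma), 0)
  list(tumour = tumour, normal = normal)
}
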