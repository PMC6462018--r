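#' Simulation configuration for the power/type-I harness
#'
#' Describes a synthetic paired cohort on the log2(TPM+1) scale. Null genes
#' are unimodal `N(mu_base, sigma^2)` in both tissues; planted oncogene
#' candidates are `N(mu_base, sigma^2)` in normal tissue and the mixture
#' `(1 - pi_t) N(mu_base, sigma^2) + pi_t N(mu_base + delta, sigma^2)` in
#' tumours; degenerate genes are null-like with a `zero_inflation` fraction
#' of entries forced to zero (to exercise the zero filter). All values are
#' clipped at 0, mimicking the floor of the log2(TPM+1) transform.
#'
#' @param n_pairs matched tumour/normal pairs; default 110.
#' @param n_null_genes null genes used for threshold calibration; default
#'   524000 (at least `1/alpha` nulls are required to resolve the quantile).
#' @param n_oc_genes planted candidate genes per replicate; default 1.
#' @param n_degenerate_genes zero-heavy genes; default 0.
#' @param pi_t tumour subgroup fraction of the planted candidates, in (0,1);
#'   default 0.25.
#' @param mu_base baseline mean; default 1.
#' @param delta high-mode offset of planted candidates (> 0); default 3.
#' @param sigma common component SD (> 0); default 1.
#' @param zero_inflation fraction of entries zeroed on degenerate genes, in
#'   \[0, 1); default 0.5.
#' @param alpha target type-I level for threshold calibration; default
#'   1.91e-6.
#' @param n_reps power replicates; default 1000.
#' @param master_seed master seed; every replicate and calibration chunk
#'   derives its own seed from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 110L, n_null_genes = 524000L,
                       n_oc_genes = 1L, n_degenerate_genes = 0L,
                       pi_t = 0.25, mu_base = 1, delta = 3, sigma = 1,
                       zero_inflation = 0.5, alpha = 1.91e-6,
                       n_reps = 1000L, master_seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              n_null_genes = as.integer(n_null_genes),
              n_oc_genes = as.integer(n_oc_genes),
              n_degenerate_genes = as.integer(n_degenerate_genes),
              pi_t = pi_t, mu_base = mu_base, delta = delta, sigma = sigma,
              zero_inflation = zero_inflation, alpha = alpha,
              n_reps = as.integer(n_reps),
              master_seed = as.integer(master_seed))
  if (cfg$n_pairs < 4) stop("n_pairs must be >= 4")
  if (cfg$n_null_genes < 0 || cfg$n_oc_genes < 0 || cfg$n_degenerate_genes < 0)
    stop("gene counts must be non-negative")
  if (!(pi_t > 0 && pi_t < 1)) stop("pi_t must lie in (0, 1)")
  if (!(delta > 0)) stop("delta must be positive")
  if (!(sigma > 0)) stop("sigma must be positive")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("zero_inflation must lie in [0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (cfg$n_reps < 1) stop("n_reps must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d pairs; genes: %d null + %d planted OC",
                     " + %d degenerate\n"),
              x$n_pairs, x$n_null_genes, x$n_oc_genes, x$n_degenerate_genes))
  cat(sprintf("  pi_t = %g, mu_base = %g, delta = %g, sigma = %g, zero_inflation = %g\n",
              x$pi_t, x$mu_base, x$delta, x$sigma, x$zero_inflation))
  cat(sprintf("  alpha = %g, n_reps = %d, master_seed = %d\n",
              x$alpha, x$n_reps, x$master_seed))
  invisible(x)
}

# deterministic per-replicate seed below 2^31 (double arithmetic is exact here)
.rep_seed <- function(master_seed, rep_index) {
  as.integer((as.numeric(master_seed) * 48271 +
                as.numeric(rep_index) * 9973) %% 2147483647)
}

# Draw the planted-OC block under the current RNG state:
# list(tumour, normal) matrices of n_oc x n_pairs.
.draw_oc_block <- function(cfg) {
  g <- cfg$n_oc_genes; n <- cfg$n_pairs
  if (!g) return(list(tumour = NULL, normal = NULL))
  hi <- matrix(rbinom(g * n, 1, cfg$pi_t), g, n)
  tum <- matrix(pmax(rnorm(g * n, cfg$mu_base + cfg$delta * hi, cfg$sigma), 0), g, n)
  nor <- matrix(pmax(rnorm(g * n, cfg$mu_base, cfg$sigma), 0), g, n)
  list(tumour = tum, normal = nor)
}

.draw_null_block <- function(n_genes, n, mu, sigma) {
  list(tumour = matrix(pmax(rnorm(n_genes * n, mu, sigma), 0), n_genes, n),
       normal = matrix(pmax(rnorm(n_genes * n, mu, sigma), 0), n_genes, n))
}

#' Generate one synthetic paired cohort
#'
#' Deterministically reproducible from `(master_seed, rep_index)`. Genes are
#' laid out as planted candidates (`oc_*`), then nulls (`null_*`), then
#' degenerate zero-heavy genes (`degen_*`); see [sim_config()] for the
#' generative model.
#'
#' @param cfg a [sim_config()].
#' @param rep_index replicate number (any integer).
#' @return A `paired_cohort` with units `LOG2TPM1`.
#' @export
generate_cohort <- function(cfg, rep_index = 1L) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config")
  n <- cfg$n_pairs
  set.seed(.rep_seed(cfg$master_seed, rep_index))
  oc <- .draw_oc_block(cfg)
  nul <- .draw_null_block(cfg$n_null_genes, n, cfg$mu_base, cfg$sigma)
  deg <- .draw_null_block(cfg$n_degenerate_genes, n, cfg$mu_base, cfg$sigma)
  if (cfg$n_degenerate_genes > 0 && cfg$zero_inflation > 0) {
    gmask <- function() matrix(rbinom(cfg$n_degenerate_genes * n, 1,
                                      cfg$zero_inflation) == 1,
                               cfg$n_degenerate_genes, n)
    deg$tumour[gmask()] <- 0
    deg$normal[gmask()] <- 0
  }
  pad <- function(prefix, k)
    if (k) sprintf("%s_%0*d", prefix, max(4, nchar(k)), seq_len(k)) else character(0)
  gid <- c(pad("oc", cfg$n_oc_genes), pad("null", cfg$n_null_genes),
           pad("degen", cfg$n_degenerate_genes))
  patients <- sprintf("P%04d", seq_len(n))
  mk <- function(which, suffix) {
    m <- rbind(oc[[which]], nul[[which]], deg[[which]])
    if (is.null(m)) m <- matrix(numeric(0), 0, n)
    dimnames(m) <- list(gid, paste0(patients, suffix))
    expr_matrix(m, "LOG2TPM1")
  }
  structure(list(tumour = mk("tumour", "_T"), normal = mk("normal", "_N"),
                 patient_ids = patients, dropped_patients = character(0)),
            class = "paired_cohort")
}

# Run the per-gene discovery pipeline on raw tumour/normal matrices and
# return the score each gene carries into threshold comparison:
# the oncogene-likeness score when the gene survives the zero filter, both
# fits converge, the tumour boundary exists and si > si_threshold; -Inf
# otherwise. Normal-tissue fits are only computed for genes that reach the
# selectivity gate (the other genes cannot score).
.pipeline_scores <- function(XT, XN, seed_t, seed_n,
                             max_zero_fraction = 0.20, si_threshold = 0.99,
                             restarts = 5L, tol = 1e-8, max_iter = 5000L,
                             sigma_floor = 1e-6) {
  g <- nrow(XT)
  scores <- rep(-Inf, g)
  if (!g) return(scores)
  zf_ok <- rowMeans(XT == 0) <= max_zero_fraction &
    rowMeans(XN == 0) <= max_zero_fraction
  idx <- which(zf_ok)
  if (!length(idx)) return(scores)
  ft <- .fit_rows(XT[idx, , drop = FALSE], seed_t + idx, restarts, tol,
                  max_iter, sigma_floor)
  ok <- ft$converged & !is.na(ft$boundary)
  si <- rep(NA_real_, length(idx))
  si[ok] <- rowMeans(XN[idx[ok], , drop = FALSE] < ft$boundary[ok])
  gate <- which(ok & !is.na(si) & si > si_threshold)
  if (!length(gate)) return(scores)
  sub <- idx[gate]
  fn <- .fit_rows(XN[sub, , drop = FALSE], seed_n + sub, restarts, tol,
                  max_iter, sigma_floor)
  okn <- fn$converged
  sc <- .score_num(ft$mu_low[gate], ft$mu_high[gate], ft$sigma[gate],
                   fn$mu_low, fn$mu_high, fn$sigma)
  scores[sub[okn]] <- sc[okn]
  scores
}

#' Calibrate the score threshold to a target type-I level
#'
#' Generates `cfg$n_null_genes` null genes (in chunks), pushes each through
#' the full discovery pipeline (zero filter, dual EM fits, selectivity gate),
#' and returns the empirical score threshold whose exceedance rate among the
#' null genes equals `cfg$alpha`: the `floor(alpha * n_null)`-th largest
#' element of the null score vector, where genes eliminated before scoring
#' carry `-Inf`. Detection downstream uses `score >= threshold`.
#'
#' @param cfg a [sim_config()]; `alpha >= 1/n_null_genes` is required, else
#'   the quantile cannot be resolved.
#' @param chunk_size genes generated and fitted per chunk; default 25000.
#' @param verbose print chunk progress.
#' @return The threshold (numeric scalar) with attributes `null_scores`
#'   (the full null score vector), `n_null`, `k`, and `alpha`.
#' @export
calibrate_threshold <- function(cfg, chunk_size = 25000L, verbose = FALSE) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config")
  n_null <- cfg$n_null_genes
  k <- floor(cfg$alpha * n_null)
  if (k < 1)
    stop(sprintf(paste0("alpha = %g is below 1/n_null_genes = %g: the null score ",
                        "quantile cannot be resolved; increase n_null_genes to ",
                        "at least %d"),
                 cfg$alpha, 1 / n_null, ceiling(1 / cfg$alpha)))
  base <- .rep_seed(cfg$master_seed, 0L)
  scores <- numeric(n_null)
  done <- 0L
  chunk <- 0L
  while (done < n_null) {
    chunk <- chunk + 1L
    g <- min(chunk_size, n_null - done)
    set.seed(.rep_seed(base, chunk))
    blk <- .draw_null_block(g, cfg$n_pairs, cfg$mu_base, cfg$sigma)
    seed_t <- .rep_seed(base, 2L * chunk)
    seed_n <- .rep_seed(base, 2L * chunk + 1L)
    scores[done + seq_len(g)] <-
      .pipeline_scores(blk$tumour, blk$normal, seed_t, seed_n)
    done <- done + g
    if (verbose)
      message(sprintf("calibration: %d / %d null genes", done, n_null))
  }
  thr <- sort(scores, decreasing = TRUE)[k]
  structure(thr, null_scores = scores, n_null = n_null, k = k,
            alpha = cfg$alpha)
}

#' Estimate detection power by Monte Carlo
#'
#' Over `cfg$n_reps` replicates, generates the planted oncogene-candidate
#' genes of each replicate cohort and reports the fraction that pass the full
#' discovery procedure: the zero filter, converged tumour and normal fits, a
#' defined tumour boundary, selectivity index > 0.99, and score at or above
#' the calibrated threshold. Also reports an exact binomial 95% CI and the
#' realised null exceedance rate at the threshold (computed on the
#' calibration nulls).
#'
#' @param cfg a [sim_config()].
#' @param threshold optional pre-computed threshold from
#'   [calibrate_threshold()] (with its `null_scores` attribute); calibrated
#'   from `cfg` when missing.
#' @param verbose print progress.
#' @return An object of class `power_estimate`: list with `power`, `type1`,
#'   `ci_low`, `ci_high`, `n_reps`, `n_detected`, `n_planted`,
#'   `threshold_used`, `master_seed`, `per_rep` (detections per replicate).
#' @export
estimate_power <- function(cfg, threshold = NULL, verbose = FALSE) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config")
  if (cfg$n_oc_genes < 1) stop("cfg$n_oc_genes must be >= 1 to estimate power")
  if (is.null(threshold)) threshold <- calibrate_threshold(cfg, verbose = verbose)
  null_scores <- attr(threshold, "null_scores")
  type1 <- if (is.null(null_scores)) NA_real_ else
    mean(is.finite(null_scores) & null_scores >= threshold)
  detected <- integer(cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    set.seed(.rep_seed(cfg$master_seed, r))
    blk <- .draw_oc_block(cfg)
    seed_t <- .rep_seed(cfg$master_seed, r) + 1L
    seed_n <- seed_t + cfg$n_oc_genes
    sc <- .pipeline_scores(blk$tumour, blk$normal, seed_t, seed_n)
    detected[r] <- sum(is.finite(sc) & sc >= threshold)
    if (verbose && r %% 100 == 0)
      message(sprintf("power: replicate %d / %d", r, cfg$n_reps))
  }
  n_planted <- cfg$n_reps * cfg$n_oc_genes
  n_det <- sum(detected)
  ci <- binom.test(n_det, n_planted)$conf.int
  structure(list(power = n_det / n_planted, type1 = type1,
                 ci_low = ci[1], ci_high = ci[2],
                 n_reps = cfg$n_reps, n_detected = n_det,
                 n_planted = n_planted,
                 threshold_used = as.numeric(threshold),
                 master_seed = cfg$master_seed, per_rep = detected),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo power estimate over %d replicates (%d planted genes)\n",
              x$n_reps, x$n_planted))
  cat(sprintf("  power = %.3f  [95%% CI %.3f, %.3f]\n",
              x$power, x$ci_low, x$ci_high))
  cat(sprintf("  score threshold = %.4f;  realised null exceedance = %.3g\n",
              x$threshold_used, x$type1))
  invisible(x)
}
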