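#' Fit a two-component equal-variance Gaussian mixture by EM
#'
#' Fits the model
#' \deqn{f(x) = \pi N(x; \mu_L, \sigma^2) + (1 - \pi) N(x; \mu_H, \sigma^2)}
#' to a vector of (typically log2(TPM+1)) expression values by expectation
#' maximisation, where \eqn{\pi} is the mixing proportion of the low
#' component and \eqn{\sigma} is shared by both components. The best of
#' `restarts` runs is kept: the first initialises from a median split of the
#' sorted values, the others from randomly perturbed split quantiles drawn in
#' (0.2, 0.8) from `seed`. Component labels are ordered so that
#' `mu_low <= mu_high`.
#'
#' @param x numeric vector of length >= 4, all finite, not all identical.
#' @param seed integer seed for the restart perturbations.
#' @param restarts number of EM runs (>= 1); default 5.
#' @param tol convergence tolerance on the absolute change in observed-data
#'   log-likelihood; default 1e-8.
#' @param max_iter iteration cap per run; default 5000.
#' @param sigma_floor lower bound applied to sigma in the M-step; a fit that
#'   hits the floor is flagged `converged = FALSE`. Default 1e-6.
#' @param tissue optional label (`"TUMOUR"` or `"NORMAL"`) carried in the fit.
#' @param trace if `TRUE`, keep the log-likelihood trace of the winning run.
#' @return An object of class `gmm2`: list with `pi`, `mu_low`, `mu_high`,
#'   `sigma`, `log_lik`, `converged`, `n_iter`, `boundary` (NA when
#'   undefined), `tissue`, `n`, and optionally `trace`.
#' @seealso [component_boundary()], [classify_samples()]
#' @examples
#' x <- c(rnorm(60, 1, 0.4), rnorm(40, 5, 0.4))
#' fit <- gmm2(x, seed = 1)
#' coef(fit)
#' @export
gmm2 <- function(x, seed = 1L, restarts = 5L, tol = 1e-8, max_iter = 5000L,
                 sigma_floor = 1e-6, tissue = NULL, trace = FALSE) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("at least 4 values are required to fit the mixture")
  if (!all(is.finite(x))) stop("all values must be finite")
  f <- .gmm_em_fit(x, as.integer(seed), as.integer(restarts), tol,
                   as.integer(max_iter), sigma_floor, isTRUE(trace))
  bnd <- .boundary_num(f$pi, f$mu_low, f$mu_high, f$sigma)
  structure(c(f, list(boundary = bnd, tissue = tissue, n = length(x),
                      seed = as.integer(seed))),
            class = "gmm2")
}

# closed-form boundary; NA when undefined (degenerate pi or equal means)
.boundary_num <- function(pi, mu_low, mu_high, sigma) {
  ifelse(pi <= 0 | pi >= 1 | mu_low >= mu_high, NA_real_,
         (mu_low + mu_high) / 2 + sigma^2 * log(pi / (1 - pi)) / (mu_high - mu_low))
}

#' @export
print.gmm2 <- function(x, digits = 4, ...) {
  cat("Two-component equal-variance Gaussian mixture (EM)\n")
  if (!is.null(x$tissue)) cat("  tissue:", x$tissue, "\n")
  cat(sprintf("  pi (low) = %.*f   mu_low = %.*f   mu_high = %.*f   sigma = %.*f\n",
              digits, x$pi, digits, x$mu_low, digits, x$mu_high, digits, x$sigma))
  cat(sprintf("  log-lik = %.*f over n = %d; %s in %d iteration(s)\n",
              digits, x$log_lik, x$n,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  low/high boundary = %s\n",
              if (is.na(x$boundary)) "undefined" else formatC(x$boundary, digits = digits, format = "f")))
  invisible(x)
}

#' @export
coef.gmm2 <- function(object, ...) {
  c(pi = object$pi, mu_low = object$mu_low, mu_high = object$mu_high,
    sigma = object$sigma)
}

#' @export
logLik.gmm2 <- function(object, ...) {
  structure(object$log_lik, df = 4L, nobs = object$n, class = "logLik")
}

#' Posterior responsibilities and class labels from a fitted mixture
#'
#' `type = "class"` labels each value LOW/HIGH via the posterior-0.5 decision
#' boundary (ties to HIGH); `type = "posterior"` returns the posterior
#' probability of the HIGH component.
#'
#' @param object a [gmm2()] fit.
#' @param newdata numeric vector of values to classify.
#' @param type `"class"` or `"posterior"`.
#' @param ... unused.
#' @export
predict.gmm2 <- function(object, newdata, type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  x <- as.numeric(newdata)
  if (type == "posterior") {
    d_lo <- object$pi * dnorm(x, object$mu_low, object$sigma)
    d_hi <- (1 - object$pi) * dnorm(x, object$mu_high, object$sigma)
    return(d_hi / (d_lo + d_hi))
  }
  classify_samples(x, component_boundary(object))
}

#' Simulate draws from a fitted mixture
#' @param object a [gmm2()] fit.
#' @param nsim number of draws.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.gmm2 <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  hi <- rbinom(nsim, 1, 1 - object$pi)
  rnorm(nsim, ifelse(hi == 1, object$mu_high, object$mu_low), object$sigma)
}

#' Histogram of the data-scale fit
#'
#' Draws a histogram of `x` with the two fitted component densities and the
#' low/high boundary overlaid.
#'
#' @param x a [gmm2()] fit.
#' @param data the values the model was fitted to.
#' @param main plot title.
#' @param ... passed to [graphics::hist()].
#' @export
plot.gmm2 <- function(x, data, main = "two-component mixture fit", ...) {
  graphics::hist(data, freq = FALSE, main = main, xlab = "expression", ...)
  xs <- seq(min(data), max(data), length.out = 400)
  graphics::lines(xs, x$pi * dnorm(xs, x$mu_low, x$sigma), col = "steelblue", lwd = 2)
  graphics::lines(xs, (1 - x$pi) * dnorm(xs, x$mu_high, x$sigma), col = "firebrick", lwd = 2)
  if (!is.na(x$boundary)) graphics::abline(v = x$boundary, lty = 2)
  invisible(x)
}

#' Low/high decision boundary of a two-component fit
#'
#' The unique point between the two means at which the posterior probability
#' of belonging to either component equals 0.5, i.e. the root of
#' \eqn{\pi N(x; \mu_L, \sigma^2) = (1-\pi) N(x; \mu_H, \sigma^2)}, in closed
#' form
#' \deqn{x^* = \frac{\mu_L + \mu_H}{2} +
#'   \frac{\sigma^2 \log(\pi / (1-\pi))}{\mu_H - \mu_L}.}
#'
#' @param fit a [gmm2()] fit, or any list with elements `pi`, `mu_low`,
#'   `mu_high`, `sigma`.
#' @return The boundary value. Errors when `mu_low == mu_high` or
#'   `pi` is 0 or 1 (the gene is not bimodal and no boundary exists).
#' @export
component_boundary <- function(fit) {
  p <- fit$pi
  if (is.na(p) || p <= 0 || p >= 1)
    stop("boundary undefined: pi must lie strictly between 0 and 1")
  if (!(fit$mu_low < fit$mu_high))
    stop("boundary undefined: component means coincide (non-bimodal fit)")
  .boundary_num(p, fit$mu_low, fit$mu_high, fit$sigma)
}

#' Classify samples against a saved boundary
#'
#' Labels each value `"HIGH"` when it is `>=` the boundary and `"LOW"`
#' otherwise (a value exactly at the boundary is HIGH). The boundary may come
#' from a different cohort than `x`, so a boundary learned on one set of
#' tumours can be reapplied to a larger tumour collection.
#'
#' @param x numeric vector of expression values (all finite).
#' @param boundary finite boundary value.
#' @return character vector of `"LOW"` / `"HIGH"`, same length as `x`.
#' @export
classify_samples <- function(x, boundary) {
  if (!is.numeric(boundary) || length(boundary) != 1 || !is.finite(boundary))
    stop("`boundary` must be a single finite number")
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("all values must be finite")
  ifelse(x >= boundary, "HIGH", "LOW")
}

# Batch fit: one row of X per gene. `seeds` is either a scalar base seed
# (per-gene seed = base + row index) or a vector of per-gene seeds.
# Returns a data.frame with the fit parameters and the closed-form boundary.
.fit_rows <- function(X, seeds, restarts = 5L, tol = 1e-8, max_iter = 5000L,
                      sigma_floor = 1e-6) {
  if (length(seeds) != nrow(X)) stop("`seeds` must have one entry per row")
  seeds <- as.integer(as.numeric(seeds) %% 2147483647)
  F <- .gmm_em_fit_rows(X, seeds, as.integer(restarts), tol,
                        as.integer(max_iter), sigma_floor)
  out <- as.data.frame(F)
  out$converged <- out$converged == 1
  out$boundary <- .boundary_num(out$pi, out$mu_low, out$mu_high, out$sigma)
  out
}
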