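#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated (the standard MSigDB dialect). Duplicate member symbols
#' within a line are deduplicated; duplicate set names across lines are an
#' error.
#'
#' @param path path to the GMT file.
#' @return list of gene sets, each a list with `name`, `description`,
#'   `members` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(list())
  }
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, members...",
                   i, length(f)))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    list(name = f[1], description = f[2], members = members)
  })
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicated gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  sets
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (q-values), preserving
#' input order. Wraps [stats::p.adjust()] after validating that every p lies
#' in (0, 1].
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in the same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("all p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher-exact gene-set overrepresentation
#'
#' For each gene set, builds the 2x2 table of query membership vs set
#' membership over the universe and computes:
#' * the one-sided (enrichment) Fisher exact p-value, i.e. the upper
#'   hypergeometric tail `P(X >= a)`;
#' * the sample odds ratio `ad / bc`, with the Haldane-Anscombe correction
#'   (+0.5 to every cell) whenever any cell is zero;
#' * a Woolf (logit-scale) 95% confidence interval on the odds ratio,
#'   computed from the same (possibly corrected) cells.
#'
#' p-values are Benjamini-Hochberg adjusted within the call (i.e. within one
#' direction, since up- and down-regulated lists are tested separately).
#'
#' @param query character vector of genes of interest (e.g. the upregulated
#'   list); must be a subset of `universe`.
#' @param universe character vector of all genes eligible to be in `query`
#'   (typically every gene surviving the expression filter).
#' @param sets gene sets from [read_gmt()].
#' @param direction label carried through to the output, `"UP"` or `"DOWN"`.
#' @return data.frame with one row per set: `set_name`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `q_value`, `direction`.
#' @export
fisher_enrichment <- function(query, universe, sets,
                              direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) stop("`universe` must be non-empty")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) absent from universe: ",
         paste(head(extra, 5), collapse = ", "),
         if (length(extra) > 5) ", ...")
  N <- length(universe)
  nq <- length(query)
  rows <- lapply(sets, function(s) {
    memb <- intersect(s$members, universe)
    K <- length(memb)
    a <- length(intersect(query, memb))
    b <- nq - a
    cc <- K - a
    d <- N - K - b
    # one-sided enrichment p: upper tail of Hypergeometric(N, K, nq) at a
    p <- phyper(a - 1, K, N - K, nq, lower.tail = FALSE)
    corr <- if (a == 0 || b == 0 || cc == 0 || d == 0) 0.5 else 0
    aa <- a + corr; bb <- b + corr; cca <- cc + corr; dd <- d + corr
    or <- (aa * dd) / (bb * cca)
    se <- sqrt(1 / aa + 1 / bb + 1 / cca + 1 / dd)
    z <- qnorm(0.975)
    data.frame(set_name = s$name, a = a, b = b, c = cc, d = d,
               odds_ratio = or,
               ci_low = exp(log(or) - z * se),
               ci_high = exp(log(or) + z * se),
               p_value = p, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out) && nrow(out)) {
    out$q_value <- bh_adjust(out$p_value)
    out <- out[, c("set_name", "a", "b", "c", "d", "odds_ratio", "ci_low",
                   "ci_high", "p_value", "q_value", "direction")]
  }
  out
}

#' Filter highly enriched gene sets
#'
#' Keeps rows passing the stringent double gate: BH-adjusted
#' `q_value < q_max` and lower bound of the odds-ratio 95% CI strictly above
#' `or_ci_min`. Both comparisons are strict.
#'
#' @param rows data.frame from [fisher_enrichment()].
#' @param q_max maximum adjusted q; default 1e-20.
#' @param or_ci_min minimum (exclusive) for the OR CI lower bound; default 20.
#' @return The filtered data.frame.
#' @export
filter_enriched <- function(rows, q_max = 1e-20, or_ci_min = 20) {
  if (is.null(rows) || !nrow(rows)) return(rows)
  if (!all(c("q_value", "ci_low") %in% colnames(rows)))
    stop("`rows` needs columns q_value and ci_low")
  rows[rows$q_value < q_max & rows$ci_low > or_ci_min, , drop = FALSE]
}
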