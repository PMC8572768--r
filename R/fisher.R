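# Exact and classical statistics used throughout the pipeline.
#
# The 2x2 layout follows the cohort-comparison convention: rows are the two
# groups, columns are with/without the property, cells
#   a b
#   c d
# For the paired allele-count test the rows are cfDNA and PBL and the columns
# are alt/ref reads.

.check_table2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (length(cells) != 4L || any(is.na(cells)) || any(cells < 0) ||
      any(cells != floor(cells)))
    stop("2x2 table cells must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero 2x2 table")
  invisible(NULL)
}

# relative tolerance used when comparing point probabilities for the
# two-sided sum (floating-point tie robustness)
.TIE_REL_TOL <- 1e-7

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum, over all tables
#' with the observed margins, of hypergeometric point probabilities no larger
#' than that of the observed table (ties included with a relative tolerance of
#' 1e-7). Reports two odds-ratio estimands: the sample cross-product ratio
#' `(a*d)/(b*c)` (with a Haldane--Anscombe 0.5 added to every cell iff any
#' cell is zero) and the conditional maximum-likelihood odds ratio of the
#' noncentral hypergeometric model, solved by bisection to relative tolerance
#' 1e-8 (0 when `a` sits at the minimum of its support, `Inf` at the maximum).
#'
#' @param a,b,c,d Non-negative integer cells, row-wise (`a`,`b` top row).
#' @return A list of class `fisher_result` with elements `p_two_sided`,
#'   `or_sample`, `or_cmle` and the table cells.
#' @examples
#' fisher_exact(5, 5, 5, 5)$p_two_sided   # 1
#' fisher_exact(2, 8, 7, 3)
#' @seealso [fisher_oracle()] for the independent enumeration used in tests.
#' @export
fisher_exact <- function(a, b, c, d) {
  .check_table2x2(a, b, c, d)
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- dens[support == a]
  p <- sum(dens[dens <= d_obs * (1 + .TIE_REL_TOL)])
  p <- min(1, max(p, .Machine$double.xmin))
  res <- list(p_two_sided = p,
              or_sample = .or_sample(a, b, c, d),
              or_cmle = .or_cmle(a, m, n, k, lo, hi, support, dens),
              a = a, b = b, c = c, d = d)
  class(res) <- "fisher_result"
  res
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact 2x2 [%d %d; %d %d]: p = %.6g, OR(sample) = %.6g, OR(cMLE) = %.6g\n",
              x$a, x$b, x$c, x$d, x$p_two_sided, x$or_sample, x$or_cmle))
  invisible(x)
}

.or_sample <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

# conditional MLE of the noncentral hypergeometric odds ratio:
# solves E[X | margins, psi] = a by bisection on log(psi)
.or_cmle <- function(a, m, n, k, lo, hi, support, dens) {
  if (lo == hi) return(NA_real_)          # degenerate support: OR not identifiable
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  ldens <- log(dens)
  e_mean <- function(lpsi) {
    lw <- ldens + support * lpsi
    lw <- lw - max(lw)
    w <- exp(lw)
    sum(support * w) / sum(w) - a
  }
  L <- 0; U <- 0
  if (e_mean(0) > 0) { while (e_mean(L) > 0) L <- L - 1 } else { while (e_mean(U) < 0) U <- U + 1 }
  if (L == U) { L <- L - 1; U <- U + 1 }
  while ((U - L) > 1e-9) {                # log-scale width ~ relative tol on psi
    mid <- (L + U) / 2
    if (e_mean(mid) < 0) L <- mid else U <- mid
  }
  exp((L + U) / 2)
}

#' Enumeration oracle for the two-sided Fisher p-value
#'
#' Computes the same point-probability two-sided p-value as [fisher_exact()]
#' by explicit enumeration of every table consistent with the margins, using
#' log-gamma (`lchoose`) arithmetic directly. This is an independent
#' verification route kept deliberately free of `dhyper`; it is intended for
#' tests and small ad-hoc checks.
#'
#' @inheritParams fisher_exact
#' @return The two-sided p-value (numeric scalar).
#' @export
fisher_oracle <- function(a, b, c, d) {
  .check_table2x2(a, b, c, d)
  margins <- c(a + b, c + d, a + c, b + d)
  if (min(margins) > 500) stop("fisher_oracle: smallest margin must be <= 500")
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  logp_obs <- logp[support == a]
  sum(exp(logp[logp <= logp_obs + log1p(.TIE_REL_TOL)]))
}

# fast p + sample OR for the triage inner loop (no cMLE)
.fisher_p_or <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- dens[support == a]
  p <- min(1, sum(dens[dens <= d_obs * (1 + .TIE_REL_TOL)]))
  c(p, .or_sample(a, b, c, d))
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()] used for the age-trend analysis.
#'
#' @param xs,ys Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 pairs")
  if (anyNA(xs) || anyNA(ys)) stop("missing values not allowed")
  if (stats::var(xs) == 0 || stats::var(ys) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(xs, ys)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()], returned in
#' the input order.
#'
#' @param pvals Probabilities in `[0, 1]`.
#' @return q-values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
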