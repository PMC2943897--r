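# Statistical kernels used by every pipeline stage. These are deliberately
# self-contained closed-form implementations; the test suite cross-checks them
# against independent routes (cor.test, t.test, p.adjust, brute-force step-up).

#' Hypothesis-test result container
#'
#' Light-weight container returned by [pearson_test()], [paired_t()] and
#' [welch_t()]. A degenerate input (zero variance where variance is required)
#' yields an *undefined* result rather than an error, so that downstream
#' screening stages can skip and log the unit instead of aborting.
#'
#' @param statistic test statistic (Pearson r, or t).
#' @param n sample size the statistic was computed from.
#' @param df degrees of freedom of the reference distribution.
#' @param p.value two-sided p-value in \[0, 1\].
#' @param method short method label.
#' @param undefined logical; `TRUE` when the statistic is undefined for the
#'   input (e.g. a constant vector).
#'
#' @return An object of class `lr_test`: a list with the fields above.
#' @export
lr_test <- function(statistic, n, df, p.value, method, undefined = FALSE) {
  structure(
    list(statistic = statistic, n = n, df = df, p.value = p.value,
         method = method, undefined = undefined),
    class = "lr_test"
  )
}

#' @export
print.lr_test <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<lr_test: %s, n = %d, undefined (degenerate input)>\n",
                x$method, x$n))
  } else {
    cat(sprintf("<lr_test: %s, statistic = %.4g, n = %d, df = %.4g, p = %.4g>\n",
                x$method, x$statistic, x$n, x$df, x$p.value))
  }
  invisible(x)
}

.undefined_test <- function(n, df, method) {
  lr_test(statistic = NA_real_, n = n, df = df, p.value = NA_real_,
          method = method, undefined = TRUE)
}

.check_numeric <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains missing or non-finite values", name), call. = FALSE)
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Computes the Pearson product-moment correlation of two vectors and the
#' two-sided p-value from the exact t transformation
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with \eqn{n-2} degrees of freedom.
#' \eqn{r = \pm 1} yields \eqn{p = 0}.
#'
#' @param x,y numeric vectors of equal length \eqn{n \ge 3}.
#' @return An [lr_test] with `statistic` = r. A constant input vector gives an
#'   undefined result (correlation is not defined), not an error.
#' @examples
#' pearson_test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
#' @export
pearson_test <- function(x, y) {
  .check_numeric(x, "x"); .check_numeric(y, "y")
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("Pearson correlation requires n >= 3", call. = FALSE)
  cx <- x - mean(x)
  cy <- y - mean(y)
  ssx <- sum(cx^2)
  ssy <- sum(cy^2)
  df <- n - 2
  if (ssx == 0 || ssy == 0) return(.undefined_test(n, df, "pearson"))
  r <- sum(cx * cy) / sqrt(ssx * ssy)
  r <- min(1, max(-1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  lr_test(statistic = r, n = n, df = df, p.value = p, method = "pearson")
}

#' Paired t-test on patient-aligned vectors
#'
#' Two-sided paired t-test on `tumor - normal` differences (values are expected
#' on the log2 scale so the test is a test on log-ratios). All-equal inputs
#' (zero-variance differences with zero mean) give an undefined result; a
#' constant non-zero difference gives an infinite statistic with \eqn{p = 0}.
#'
#' @param tumor,normal numeric vectors of equal length \eqn{n \ge 2}, aligned
#'   by patient.
#' @return An [lr_test] with `df = n - 1`.
#' @export
paired_t <- function(tumor, normal) {
  .check_numeric(tumor, "tumor"); .check_numeric(normal, "normal")
  if (length(tumor) != length(normal))
    stop("'tumor' and 'normal' must have equal length", call. = FALSE)
  n <- length(tumor)
  if (n < 2) stop("paired t-test requires n >= 2", call. = FALSE)
  d <- tumor - normal
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    if (m == 0) return(.undefined_test(n, df, "paired t"))
    return(lr_test(statistic = sign(m) * Inf, n = n, df = df, p.value = 0,
                   method = "paired t"))
  }
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df)
  lr_test(statistic = tstat, n = n, df = df, p.value = p, method = "paired t")
}

#' Welch two-sample t-test (unequal variance)
#'
#' Two-sided t-test with the Welch statistic and Welch-Satterthwaite degrees of
#' freedom, for unpaired designs (e.g. tumors versus independent normals).
#'
#' @param a,b numeric vectors, each of length \eqn{\ge 2}.
#' @return An [lr_test]. Two constant equal groups give an undefined result.
#' @export
welch_t <- function(a, b) {
  .check_numeric(a, "a"); .check_numeric(b, "b")
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("welch_t requires >= 2 values per group", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  n <- na + nb
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(.undefined_test(n, NA_real_, "welch t"))
    return(lr_test(statistic = sign(mean(a) - mean(b)) * Inf, n = n,
                   df = NA_real_, p.value = 0, method = "welch t"))
  }
  sa <- va / na
  sb <- vb / nb
  se2 <- sa + sb
  df <- se2^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  lr_test(statistic = tstat, n = n, df = df, p.value = p, method = "welch t")
}

#' Bonferroni correction
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m positive integer, the size of the test family.
#' @return `pmin(1, m * p)`, in input order.
#' @export
bonferroni <- function(p, m) {
  .check_numeric(p, "p")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (length(m) != 1 || is.na(m) || m < 1 || m != as.integer(m))
    stop("'m' must be a positive integer", call. = FALSE)
  pmin(1, m * p)
}

#' Benjamini-Hochberg step-up adjusted p-values (q-values)
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, m \, p_{(j)} / j)}, returned in input
#' order. Monotone in the input and never smaller than the raw p-value.
#'
#' @param p numeric vector of p-values in \[0, 1\]; may be empty.
#' @return numeric vector of adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  .check_numeric(p, "p")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
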