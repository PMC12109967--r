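# Cohort-comparison statistics used in the clinical evaluation.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability (minimum-likelihood) two-sided p: conditioning on the
#' table margins, the p-value is the sum of hypergeometric probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (with the conventional 1e-7 relative tolerance on ties). This is the
#' convention used for categorical comparisons in clinical baseline tables.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_two_sided(9, 6, 5, 5)   # 0.697
#' fisher_exact_two_sided(6, 9, 6, 4)   # 0.428
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) return(1)
  m <- a + c          # column-1 margin
  n <- b + d          # column-2 margin
  k <- a + b          # row-1 margin
  lo <- max(0, k - n)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  p <- sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)])
  min(p, 1)
}

#' Mann-Whitney U test (midranks; exact for small samples)
#'
#' Computes U from midrank sums. For combined sample sizes of at most
#' `exact_max` the two-sided p is exact, by enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments of the pooled midranks
#' (p = proportion of assignments whose U is at least as far from the null
#' mean `n_a * n_b / 2` as the observed U). Larger samples use the normal
#' approximation with the tie-corrected variance, without continuity
#' correction.
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @param exact_max Largest combined size for the enumeration branch
#'   (default 12).
#' @return List with `u` (statistic for `group_a`), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 12) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (anyNA(group_a) || anyNA(group_b)) stop("missing values not allowed")
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= exact_max) {
    combs <- utils::combn(n, na)
    rank_sums <- colSums(matrix(r[combs], nrow = na))
    u_all <- rank_sums - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal"))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(u = u, p = min(p, 1), method = method)
}

#' Paired t-test on treated vs untreated values
#'
#' Standard paired Student t-test on the within-pair differences, as used
#' for per-gene treated-vs-untreated panels.
#'
#' @param treated,untreated Numeric vectors of equal length (>= 2 pairs).
#' @return List with `t` (statistic), `p` (two-sided), `df`.
#' @examples
#' paired_t_test(c(2.1, 2.5, 1.9, 2.4), c(1.0, 1.2, 0.9, 1.1))
#' @export
paired_t_test <- function(treated, untreated) {
  if (length(treated) != length(untreated))
    stop("treated and untreated must have equal length")
  if (length(treated) < 2) stop("need at least 2 pairs")
  d <- treated - untreated
  if (stats::sd(d) == 0)
    stop("differences have zero variance; t statistic undefined")
  ht <- stats::t.test(treated, untreated, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Center and interquartile range of a clinical variable
#'
#' Summarizes a numeric column as mean or median with the 25th/75th
#' percentiles. The default percentile convention places quartiles at the
#' `(n + 1) * p` order statistic (`stats::quantile` type 6), the
#' convention of common clinical-statistics software.
#'
#' @param values Non-empty numeric vector.
#' @param kind `"mean"` or `"median"`.
#' @param quantile_type Passed to [stats::quantile()] (default 6).
#' @return List with `center`, `q25`, `q75`.
#' @examples
#' group_summary(c(1, 2, 3), kind = "mean")
#' @export
group_summary <- function(values, kind = c("mean", "median"),
                          quantile_type = 6) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input")
  if (anyNA(values)) stop("missing values not allowed")
  q <- stats::quantile(values, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  list(center = if (kind == "mean") mean(values) else
                  stats::median(values),
       q25 = q[1], q75 = q[2])
}
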