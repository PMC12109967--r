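# Independent brute-force oracles. These restate the decision rules and
# statistics from first principles, deliberately avoiding the package's
# own code paths, so that agreement is evidence and not tautology.

# Activation rule, plain scalar restatement: CD36 gate, then the
# at-least-half-of-evaluable-Nrf2-genes rule. `nrf2` holds evaluable
# ratios only.
oracle_classify <- function(cd36, nrf2, lower = 0.94, upper = 1.06) {
  if (is.na(cd36)) return(NA_character_)
  if (cd36 < lower) return("NonActivator")
  if (cd36 <= upper) return("Uncertain")
  if (length(nrf2) == 0) return("Uncertain")
  hits <- sum(nrf2 > upper)
  if (hits >= length(nrf2) / 2) "Activator" else "NonActivator"
}

# EULAR grid as an explicit 3x3 truth table over improvement band x
# attained-activity band (classical DAS28 cut-points).
oracle_eular <- function(m0, m3) {
  d <- m0 - m3
  imp <- if (d > 1.2) "major" else if (d > 0.6) "interm" else "none"
  att <- if (m3 <= 3.2) "low" else if (m3 <= 5.1) "mid" else "high"
  cell <- list(
    low  = c(major = "Good",     interm = "Moderate", none = "None"),
    mid  = c(major = "Moderate", interm = "Moderate", none = "None"),
    high = c(major = "Moderate", interm = "None",     none = "None"))
  unname(cell[[att]][[imp]])
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from the multiplicative binomial form
# (conditioning on the column margin, unlike the package's dhyper
# parameterization over the row margin).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  av <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, av) * choose(r2, c1 - av) / choose(n, c1)
  min(sum(prob[prob <= prob[av == a] * (1 + 1e-7)]), 1)
}

# Exact two-sided Mann-Whitney p by enumeration, with U computed by
# direct pair counting (not rank sums).
oracle_mw_exact <- function(a, b) {
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  mu <- na * length(b) / 2
  u_obs <- u_of(a, b)
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Quick constructor for a one-sample long profile table.
make_profile <- function(sample_id, cd36, nrf2,
                         genes = nrf2_genes()[seq_along(nrf2)],
                         cd36_evaluable = TRUE,
                         nrf2_evaluable = rep(TRUE, length(nrf2))) {
  data.frame(
    sample_id = sample_id,
    gene = c("CD36", genes),
    ratio = c(cd36, nrf2),
    evaluable = c(cd36_evaluable, nrf2_evaluable),
    stringsAsFactors = FALSE)
}

# Raw Ct table for one sample with chosen per-(gene, condition) mean Cts,
# duplicated into two identical technical replicates.
make_ct <- function(sample_id, cts) {
  # cts: data.frame(gene, condition, ct)
  data.frame(
    sample_id = sample_id,
    condition = rep(cts$condition, each = 2),
    gene = rep(cts$gene, each = 2),
    replicate = rep(1:2, nrow(cts)),
    ct = rep(cts$ct, each = 2),
    stringsAsFactors = FALSE)
}
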