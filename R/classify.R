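# Activation-status decision algorithm (CD36 gate + Nrf2 majority rule).

#' Classify tmTNF reverse-signaling activation status
#'
#' Applies the two-stage decision rule to each sample's fold-change profile:
#' \enumerate{
#'   \item CD36 gate: a CD36 treated/untreated ratio strictly below the
#'     lower band edge calls the sample a `NonActivator`; a ratio inside
#'     the band (boundaries included) is `Uncertain` -- the modulation is
#'     within measurement noise.
#'   \item Nrf2 majority: when CD36 clears the upper edge, the sample is an
#'     `Activator` if at least 50% of its *evaluable* Nrf2 target genes
#'     have ratios strictly above the upper edge, otherwise a
#'     `NonActivator`. Non-amplified genes are excluded from the
#'     denominator; if no Nrf2 gene is evaluable the call is `Uncertain`.
#' }
#' Samples whose CD36 ratio is not evaluable are refused (status `NA`,
#' rule `"refused_cd36_not_evaluable"`): the gate cannot be applied.
#'
#' @param profiles Long fold-change data frame (`sample_id`, `gene`,
#'   `ratio`, `evaluable`), e.g. `build_profiles(ct)$profiles`.
#' @param band Numeric `c(lower, upper)` decision band, usually
#'   [cv_band()]. Must satisfy `lower < 1 < upper`.
#' @return Data frame with one row per sample: `sample_id`, `status`
#'   (`"Activator"`, `"NonActivator"`, `"Uncertain"`, or `NA` when
#'   refused), `cd36_ratio`, `nrf2_hits`, `n_evaluable_nrf2`, and `rule`
#'   (which rule fired).
#' @examples
#' prof <- data.frame(
#'   sample_id = "d1",
#'   gene = c("CD36", nrf2_genes()),
#'   ratio = c(1.20, 1.10, 1.08, 1.12, 0.90, 1.00, 1.02),
#'   evaluable = TRUE)
#' classify_activation(prof)
#' @export
classify_activation <- function(profiles, band = cv_band(0.06)) {
  stopifnot(length(band) == 2)
  lower <- band[[1]]; upper <- band[[2]]
  if (!(lower < 1 && 1 < upper))
    stop("band must satisfy lower < 1 < upper")
  need <- c("sample_id", "gene", "ratio", "evaluable")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop("profiles missing columns: ", paste(miss, collapse = ", "))
  profiles$gene <- normalize_gene(profiles$gene)

  samples <- unique(profiles$sample_id)
  cd36 <- profiles[profiles$gene == "CD36", , drop = FALSE]
  i <- match(samples, cd36$sample_id)
  cd36_ratio <- cd36$ratio[i]
  cd36_ok <- cd36$evaluable[i] %in% TRUE & !is.na(cd36_ratio)

  nrf2 <- profiles[profiles$gene %in% nrf2_genes(), , drop = FALSE]
  if (nrow(nrf2)) {
    ev   <- rowsum(as.numeric(nrf2$evaluable %in% TRUE), nrf2$sample_id)
    hit  <- rowsum(as.numeric(nrf2$evaluable %in% TRUE &
                              !is.na(nrf2$ratio) & nrf2$ratio > upper),
                   nrf2$sample_id)
    j <- match(samples, rownames(ev))
    n_eval <- ifelse(is.na(j), 0L, as.integer(ev[j]))
    n_hit  <- ifelse(is.na(j), 0L, as.integer(hit[j]))
  } else {
    n_eval <- n_hit <- rep(0L, length(samples))
  }

  status <- rep(NA_character_, length(samples))
  rule   <- rep("refused_cd36_not_evaluable", length(samples))

  low  <- cd36_ok & cd36_ratio < lower
  mid  <- cd36_ok & cd36_ratio >= lower & cd36_ratio <= upper
  high <- cd36_ok & cd36_ratio > upper

  status[low] <- "NonActivator"; rule[low] <- "cd36_below_band"
  status[mid] <- "Uncertain";    rule[mid] <- "cd36_within_band"
  none <- high & n_eval == 0
  status[none] <- "Uncertain";   rule[none] <- "no_evaluable_nrf2"
  act <- high & n_eval > 0 & n_hit / pmax(n_eval, 1L) >= 0.5
  status[act] <- "Activator";    rule[act] <- "nrf2_majority_up"
  non <- high & n_eval > 0 & !act
  status[non] <- "NonActivator"; rule[non] <- "nrf2_majority_not_up"

  data.frame(sample_id = samples, status = status, cd36_ratio = cd36_ratio,
             nrf2_hits = n_hit, n_evaluable_nrf2 = n_eval, rule = rule,
             stringsAsFactors = FALSE)
}

#' Consensus activation call across repeated experiments
#'
#' Borderline samples may be re-assayed; the per-experiment calls are
#' merged into a consensus. Decisive (non-`Uncertain`) calls vote by
#' majority; `Uncertain` calls abstain. A tie among decisive calls, or no
#' decisive call at all, leaves the sample `Uncertain`.
#'
#' @param statuses Character vector of per-experiment statuses
#'   (`"Activator"`, `"NonActivator"`, `"Uncertain"`) for one sample.
#' @return A single consensus status string.
#' @examples
#' consensus_call(c("Uncertain", "Activator", "Activator"))
#' consensus_call(c("Activator", "NonActivator"))  # tie -> Uncertain
#' @export
consensus_call <- function(statuses) {
  statuses <- as.character(statuses)
  if (length(statuses) < 1) stop("need at least one call")
  ok <- c("Activator", "NonActivator", "Uncertain")
  if (!all(statuses %in% ok))
    stop("unknown status: ", paste(setdiff(statuses, ok), collapse = ", "))
  n_act <- sum(statuses == "Activator")
  n_non <- sum(statuses == "NonActivator")
  if (n_act > n_non) "Activator"
  else if (n_non > n_act) "NonActivator"
  else "Uncertain"
}
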