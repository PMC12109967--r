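# Ct-level cohort simulator with calibrated replicate noise and dropout.

#' Simulation configuration
#'
#' Parameters of the synthetic qPCR cohort generator. The defaults encode
#' the study conditions the assay assumes: duplicate technical replicates,
#' a fold-change-ratio coefficient of variation of 0.06 (the calibrated
#' assay CV), occasional amplification dropout (Ct beyond 40 cycles), an
#' activator fold-change center of 1.5 on CD36 and all Nrf2 targets, and
#' an unmodulated (1.0) non-activator center.
#'
#' Replicate noise is injected as independent Gaussian perturbations on
#' the Ct scale. The per-well Ct standard deviation is derived in closed
#' form so that the ratio computed downstream -- from four
#' replicate-averaged Ct values via `2^-ddCt` -- is lognormal with
#' coefficient of variation exactly `ratio_cv`:
#' `sd_ct = sqrt(log(1 + ratio_cv^2)) * sqrt(n_tech_reps) / (2 * log(2))`.
#' Effect sizes shift the treated-condition Ct of target genes by
#' `-log2(effect)` cycles; GAPDH is never moved by treatment.
#'
#' @param n_activators,n_nonactivators Donors per class.
#' @param effect_size_activator Fold-change center (median ratio) of CD36
#'   and the Nrf2 genes in activators (default 1.5).
#' @param effect_size_nonactivator Same for non-activators (default 1.0,
#'   no modulation; set below 0.94 to exercise the low gate).
#' @param ratio_cv Coefficient of variation of the replicate-derived
#'   fold-change ratios (default 0.06).
#' @param dropout_prob Probability that a gene fails to amplify in one
#'   (sample, condition) pair (default 0.05).
#' @param n_tech_reps Technical replicates per well (default 2).
#' @param baseline_ct_range Plausible Ct interval for expressed genes
#'   (default 18-32 cycles).
#' @param concordance Probability that a simulated activator is a clinical
#'   responder, and a non-activator a non-responder (default 1).
#' @param seed RNG seed for [simulate_cohort()].
#' @return List of class `sim_config`.
#' @examples
#' sim_config(n_activators = 3, n_nonactivators = 2)
#' @export
sim_config <- function(n_activators = 10, n_nonactivators = 10,
                       effect_size_activator = 1.5,
                       effect_size_nonactivator = 1.0,
                       ratio_cv = 0.06, dropout_prob = 0.05,
                       n_tech_reps = 2, baseline_ct_range = c(18, 32),
                       concordance = 1.0, seed = 1L) {
  stopifnot(n_activators >= 0, n_nonactivators >= 0,
            effect_size_activator > 0, effect_size_nonactivator > 0,
            ratio_cv >= 0, dropout_prob >= 0, dropout_prob <= 1,
            n_tech_reps >= 1, length(baseline_ct_range) == 2,
            baseline_ct_range[1] > 0,
            baseline_ct_range[1] < baseline_ct_range[2],
            concordance >= 0, concordance <= 1)
  structure(list(n_activators = as.integer(n_activators),
                 n_nonactivators = as.integer(n_nonactivators),
                 effect_size_activator = effect_size_activator,
                 effect_size_nonactivator = effect_size_nonactivator,
                 ratio_cv = ratio_cv, dropout_prob = dropout_prob,
                 n_tech_reps = as.integer(n_tech_reps),
                 baseline_ct_range = baseline_ct_range,
                 concordance = concordance, seed = as.integer(seed)),
            class = "sim_config")
}

# Per-well Ct SD that propagates to a ratio CV of `ratio_cv` after
# averaging n replicates and differencing four well means in the ddCt.
ct_noise_sd <- function(ratio_cv, n_tech_reps) {
  sigma_log <- sqrt(log(1 + ratio_cv^2))   # SD of log(ratio), lognormal CV
  sigma_log * sqrt(n_tech_reps) / (2 * log(2))
}

#' Simulate the Ct table of one donor
#'
#' Generates raw Ct rows for GAPDH plus the seven target genes, both
#' conditions, `n_tech_reps` replicates each. Each gene draws a baseline Ct
#' uniformly from `baseline_ct_range` (shared between conditions); the
#' treated-condition Ct of target genes is shifted by `-log2(effect)`;
#' every well gets independent Gaussian Ct noise calibrated to the
#' configured ratio CV; and each (gene, condition) pair drops out with
#' probability `dropout_prob`, recorded as Ct 45 (beyond the 40-cycle
#' cutoff).
#'
#' @param status `"Activator"` or `"NonActivator"` (selects the effect
#'   size).
#' @param config A [sim_config()].
#' @param seed Integer seed for this donor.
#' @param sample_id Sample identifier (default derived from the seed).
#' @return Raw Ct data frame (`sample_id`, `condition`, `gene`,
#'   `replicate`, `ct`).
#' @examples
#' cfg <- sim_config(ratio_cv = 0, dropout_prob = 0)
#' ct <- simulate_donor("Activator", cfg, seed = 1)
#' head(ct)
#' @export
simulate_donor <- function(status, config = sim_config(), seed = 1L,
                           sample_id = paste0("donor_", seed)) {
  if (!status %in% c("Activator", "NonActivator"))
    stop("status must be 'Activator' or 'NonActivator'")
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  as.data.frame(simulate_donor_impl(status, config, sample_id))
}

# RNG-consuming core; callers manage set.seed(). Returns plain column
# vectors in a list so cohort assembly can concatenate without rbind.
simulate_donor_impl <- function(status, config, sample_id) {
  effect <- if (status == "Activator") config$effect_size_activator
            else config$effect_size_nonactivator
  panel <- assay_panel()
  targets <- setdiff(panel, "GAPDH")
  nrep <- config$n_tech_reps
  sd_ct <- if (config$ratio_cv > 0) ct_noise_sd(config$ratio_cv, nrep)
           else 0

  baseline <- stats::runif(length(panel), config$baseline_ct_range[1],
                           config$baseline_ct_range[2])
  names(baseline) <- panel

  grid <- expand.grid(gene = panel, condition = c("NT", "T"),
                      replicate = seq_len(nrep),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ct <- baseline[grid$gene]
  shift <- grid$condition == "T" & grid$gene %in% targets
  ct[shift] <- ct[shift] - log2(effect)
  if (sd_ct > 0) ct <- ct + stats::rnorm(nrow(grid), 0, sd_ct)

  # gene-level dropout per (gene, condition) pair, all replicates lost
  pairs <- expand.grid(gene = panel, condition = c("NT", "T"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dropped <- stats::runif(nrow(pairs)) < config$dropout_prob
  drop_key <- paste(pairs$gene, pairs$condition)[dropped]
  is_dropped <- paste(grid$gene, grid$condition) %in% drop_key
  ct[is_dropped] <- 45

  list(sample_id = rep(sample_id, nrow(grid)), condition = grid$condition,
       gene = grid$gene, replicate = grid$replicate, ct = as.numeric(ct))
}

#' Simulate a full cohort with ground truth and clinical records
#'
#' Generates `n_activators + n_nonactivators` donors, their raw Ct tables,
#' and synthetic clinical records. Each donor's clinical responder status
#' equals their activation truth label with probability `concordance`
#' (flipped otherwise). DAS28 pairs are drawn inside unambiguous EULAR
#' cells: responders get a Good-cell pair (improvement > 1.2 ending at or
#' below 3.2), non-responders an improvement of at most 0.6, so the EULAR
#' mapping reproduces the assigned responder status exactly. Antibody-class
#' drugs are assigned round-robin.
#'
#' @param config A [sim_config()]; its `seed` drives all randomness.
#' @return List of class `sim_cohort`: `ct_table` (all donors stacked),
#'   `truth` (`sample_id`, `status`), `clinical` (`patient_id`, `drug`,
#'   `drug_class`, `das28_m0`, `das28_m3`, `evolution`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_activators = 2,
#'                                      n_nonactivators = 2, seed = 7))
#' cohort$truth
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_activators + config$n_nonactivators
  if (n == 0) stop("cohort must contain at least one donor")
  status <- c(rep("Activator", config$n_activators),
              rep("NonActivator", config$n_nonactivators))
  ids <- sprintf("donor_%03d", seq_len(n))

  set.seed(config$seed)
  parts <- lapply(seq_len(n), function(i) {
    simulate_donor_impl(status[i], config, ids[i])
  })
  ct_table <- data.frame(
    sample_id = unlist(lapply(parts, `[[`, "sample_id")),
    condition = unlist(lapply(parts, `[[`, "condition")),
    gene      = unlist(lapply(parts, `[[`, "gene")),
    replicate = unlist(lapply(parts, `[[`, "replicate")),
    ct        = unlist(lapply(parts, `[[`, "ct")),
    stringsAsFactors = FALSE
  )

  responder <- ifelse(stats::runif(n) < config$concordance,
                      status == "Activator", status != "Activator")
  m0 <- stats::runif(n, 3.5, 6.5)
  # responders: Good cell (delta > 1.2, endpoint <= 3.2); non-responders:
  # delta <= 0.6 (None cell regardless of endpoint)
  m3 <- ifelse(responder,
               stats::runif(n, 1.0, pmin(3.2, m0 - 1.25)),
               m0 - stats::runif(n, -0.5, 0.55))
  drugs <- c("ADA", "GOL", "IFX")
  drug <- drugs[(seq_len(n) - 1) %% length(drugs) + 1]

  structure(list(
    ct_table = ct_table,
    truth = data.frame(sample_id = ids, status = status,
                       stringsAsFactors = FALSE),
    clinical = data.frame(patient_id = ids, drug = drug,
                          drug_class = "antibody",
                          das28_m0 = round(m0, 2), das28_m3 = round(m3, 2),
                          evolution = ifelse(responder, "+", "-"),
                          stringsAsFactors = FALSE)
  ), class = "sim_cohort")
}
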