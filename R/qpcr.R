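# Ct-level quantitation: replicate collapse, ddCt fold changes, CV band.

#' Collapse technical replicates to one mean Ct per well group
#'
#' Technical replicates of the same (sample, condition, gene) well are
#' averaged on the Ct scale, using amplified replicates only. A replicate is
#' amplified when its Ct is present and at most `cutoff` cycles; wells where
#' no replicate amplified are flagged, not imputed.
#'
#' @param ct_table Data frame with columns `sample_id`, `condition`
#'   (`"T"`/`"NT"`), `gene`, `replicate`, `ct`. `ct` may be `NA` for a
#'   non-amplified well.
#' @param cutoff Non-amplification cutoff in cycles (default 40): Ct values
#'   strictly greater than this are treated as not amplified.
#' @return Data frame with one row per (sample_id, condition, gene):
#'   `ct_mean` (mean over amplified replicates, `NA` if none) and
#'   `amplified` (logical).
#' @examples
#' ct <- data.frame(sample_id = "s1", condition = "T", gene = "CD36",
#'                  replicate = 1:2, ct = c(24.0, 24.2))
#' collapse_replicates(ct)
#' @export
collapse_replicates <- function(ct_table, cutoff = 40) {
  ct_table <- validate_ct_table(ct_table)
  amp <- !is.na(ct_table$ct) & ct_table$ct <= cutoff
  key <- paste(ct_table$sample_id, ct_table$condition, ct_table$gene,
               sep = "\r")
  sums   <- rowsum(ifelse(amp, ct_table$ct, 0), key)
  counts <- rowsum(as.numeric(amp), key)
  first  <- !duplicated(key)
  ord    <- match(rownames(sums), key[first])
  out <- data.frame(
    sample_id = ct_table$sample_id[first][ord],
    condition = ct_table$condition[first][ord],
    gene      = ct_table$gene[first][ord],
    ct_mean   = as.numeric(ifelse(counts > 0, sums / counts, NA)),
    amplified = as.logical(counts > 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$sample_id, out$gene, out$condition), , drop = FALSE]
}

#' Relative fold change by the 2^-ddCt method
#'
#' Treated-vs-untreated expression ratio of a target gene normalized to the
#' reference gene: `2^-[(ct_gene_t - ct_ref_t) - (ct_gene_nt - ct_ref_nt)]`.
#' Assumes 100% amplification efficiency for both amplicons. All arguments
#' are vectorized; any `NA` input (a non-amplified well) yields an `NA`
#' ratio so the gene can be flagged non-evaluable upstream.
#'
#' @param ct_gene_t,ct_ref_t Ct of target and reference gene, treated.
#' @param ct_gene_nt,ct_ref_nt Ct of target and reference gene, untreated.
#' @return Numeric vector of strictly positive fold-change ratios.
#' @examples
#' fold_change(24, 20, 25, 20)          # one-cycle gain -> 2
#' fold_change(26.5, 20, 25, 20)        # 2^-1.5
#' @export
fold_change <- function(ct_gene_t, ct_ref_t, ct_gene_nt, ct_ref_nt) {
  ddct <- (ct_gene_t - ct_ref_t) - (ct_gene_nt - ct_ref_nt)
  2^(-ddct)
}

#' Per-sample fold-change profiles from a raw Ct table
#'
#' Runs replicate collapse and ddCt quantitation for every sample in the
#' table. A target gene is evaluable in a sample when it amplified in both
#' conditions and GAPDH amplified in both conditions; non-evaluable genes
#' carry no ratio. A sample whose GAPDH failed in either condition, or that
#' lacks a condition entirely, cannot be normalized and is reported in
#' `$invalid` rather than profiled.
#'
#' @param ct_table Raw Ct data frame (see [collapse_replicates()]).
#' @param panel Gene panel; must contain `"GAPDH"`. Target genes are the
#'   panel minus GAPDH.
#' @param cutoff Non-amplification cutoff in cycles.
#' @return List with:
#'   \describe{
#'     \item{profiles}{long data frame `sample_id`, `gene`, `ratio`,
#'       `evaluable` (one row per sample x target gene).}
#'     \item{n_evaluable_nrf2}{data frame `sample_id`,
#'       `n_evaluable_nrf2`.}
#'     \item{invalid}{data frame `sample_id`, `reason` for samples that
#'       could not be profiled.}
#'   }
#' @examples
#' cfg <- sim_config(n_activators = 1, n_nonactivators = 0, ratio_cv = 0)
#' ct <- simulate_donor("Activator", cfg, seed = 1)
#' build_profiles(ct)$profiles
#' @export
build_profiles <- function(ct_table, panel = assay_panel(), cutoff = 40) {
  stopifnot("GAPDH" %in% panel)
  targets <- setdiff(panel, "GAPDH")
  if (nrow(ct_table) == 0) {
    warning("empty Ct table: no profiles built")
    return(list(
      profiles = data.frame(sample_id = character(), gene = character(),
                            ratio = numeric(), evaluable = logical()),
      n_evaluable_nrf2 = data.frame(sample_id = character(),
                                    n_evaluable_nrf2 = integer()),
      invalid = data.frame(sample_id = character(), reason = character())
    ))
  }
  coll <- collapse_replicates(ct_table, cutoff = cutoff)
  samples <- unique(coll$sample_id)

  pick <- function(gene, cond, col) {
    idx <- match(paste(samples, cond, gene, sep = "\r"),
                 paste(coll$sample_id, coll$condition, coll$gene, sep = "\r"))
    coll[[col]][idx]
  }
  gap_t_ok  <- pick("GAPDH", "T",  "amplified") %in% TRUE
  gap_nt_ok <- pick("GAPDH", "NT", "amplified") %in% TRUE
  has_t  <- samples %in% coll$sample_id[coll$condition == "T"]
  has_nt <- samples %in% coll$sample_id[coll$condition == "NT"]

  reason <- rep(NA_character_, length(samples))
  reason[!has_t | !has_nt] <- "missing condition"
  reason[is.na(reason) & !(gap_t_ok & gap_nt_ok)] <-
    "GAPDH not amplified in at least one condition"
  valid <- is.na(reason)

  gap_t  <- pick("GAPDH", "T",  "ct_mean")
  gap_nt <- pick("GAPDH", "NT", "ct_mean")

  prof <- do.call(rbind, lapply(targets, function(g) {
    amp_ok <- (pick(g, "T", "amplified") %in% TRUE) &
              (pick(g, "NT", "amplified") %in% TRUE)
    evaluable <- valid & amp_ok
    ratio <- ifelse(evaluable,
                    fold_change(pick(g, "T", "ct_mean"), gap_t,
                                pick(g, "NT", "ct_mean"), gap_nt),
                    NA_real_)
    data.frame(sample_id = samples, gene = g, ratio = ratio,
               evaluable = evaluable, stringsAsFactors = FALSE)
  }))
  prof <- prof[prof$sample_id %in% samples[valid], , drop = FALSE]
  prof <- prof[order(prof$sample_id, prof$gene), , drop = FALSE]
  rownames(prof) <- NULL

  nev <- prof[prof$gene %in% nrf2_genes(), , drop = FALSE]
  n_ev <- rowsum(as.numeric(nev$evaluable), nev$sample_id)
  nev_df <- data.frame(sample_id = rownames(n_ev),
                       n_evaluable_nrf2 = as.integer(n_ev),
                       stringsAsFactors = FALSE)
  rownames(nev_df) <- NULL

  list(
    profiles = prof,
    n_evaluable_nrf2 = nev_df,
    invalid = data.frame(sample_id = samples[!valid],
                         reason = reason[!valid],
                         stringsAsFactors = FALSE)
  )
}

#' Coefficient of variation of fold-change ratios
#'
#' Sample standard deviation divided by the mean. Used to calibrate the
#' indecision band of the activation classifier from repeated quantification
#' of one sample.
#'
#' @param ratios Numeric vector, length at least 2, nonzero mean.
#' @return The CV (unitless).
#' @examples
#' coefficient_of_variation(c(0.9, 1.1))
#' @export
coefficient_of_variation <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) < 2) stop("need at least 2 values to compute a CV")
  m <- mean(ratios)
  if (m == 0) stop("mean of ratios is zero; CV undefined")
  stats::sd(ratios) / m
}

#' Indecision band around a fold change of 1
#'
#' A measured ratio within `(1 - cv, 1 + cv)` is indistinguishable from no
#' modulation given the assay's replicate variability. With the calibrated
#' CV of 0.06 this is the (0.94, 1.06) band used by the activation
#' algorithm.
#'
#' @param cv Coefficient of variation, strictly between 0 and 1.
#' @return Named numeric vector `c(lower = 1 - cv, upper = 1 + cv)`.
#' @examples
#' cv_band(0.06)
#' @export
cv_band <- function(cv = 0.06) {
  if (!is.numeric(cv) || length(cv) != 1 || is.na(cv) || cv <= 0 || cv >= 1)
    stop("cv must be a single number strictly between 0 and 1")
  c(lower = 1 - cv, upper = 1 + cv)
}

# Internal: check/coerce a raw Ct table.
validate_ct_table <- function(ct_table) {
  need <- c("sample_id", "condition", "gene", "replicate", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("Ct table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(ct_table) == 0) stop("Ct table is empty")
  ct_table$sample_id <- as.character(ct_table$sample_id)
  ct_table$gene <- normalize_gene(ct_table$gene)
  ct_table$condition <- toupper(as.character(ct_table$condition))
  if (!all(ct_table$condition %in% c("T", "NT")))
    stop("condition must be 'T' (treated) or 'NT' (untreated)")
  bad <- !is.na(ct_table$ct) & ct_table$ct <= 0
  if (any(bad)) stop("Ct values must be positive or NA (non-amplified)")
  ct_table
}
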