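# CSV schemas, the packaged clinical fixture, configuration, and the
# end-to-end pipeline.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the analysis path. Stimulation
#' metadata (drug concentration, duration) is carried as provenance
#' annotation only and never enters a computation.
#'
#' @param cv Assay coefficient of variation defining the decision band
#'   (default 0.06).
#' @param non_amplified_ct_cutoff Ct cutoff in cycles beyond which a well
#'   is non-amplified (default 40).
#' @param gene_panel Gene panel; must include GAPDH, all names unique.
#' @param grid An [eular_grid()].
#' @param uncertain_policy Policy for `Uncertain` calls in
#'   [concordance()].
#' @param quantile_type Percentile convention for [group_summary()].
#' @param stimulation Provenance metadata list (default: 10 ug/mL TNFi,
#'   16 h).
#' @return List of class `pipeline_config`.
#' @examples
#' pipeline_config()$cv
#' @export
pipeline_config <- function(cv = 0.06, non_amplified_ct_cutoff = 40,
                            gene_panel = assay_panel(),
                            grid = eular_grid(),
                            uncertain_policy = "exclude",
                            quantile_type = 6,
                            stimulation = list(dose = "10 ug/mL",
                                               duration = "16 h")) {
  gene_panel <- normalize_gene(gene_panel)
  if (anyDuplicated(gene_panel)) stop("gene_panel contains duplicates")
  if (!"GAPDH" %in% gene_panel) stop("gene_panel must include GAPDH")
  structure(list(cv = cv,
                 non_amplified_ct_cutoff = non_amplified_ct_cutoff,
                 gene_panel = gene_panel, grid = grid,
                 uncertain_policy = uncertain_policy,
                 quantile_type = quantile_type, stimulation = stimulation),
            class = "pipeline_config")
}

#' Read / write the pipeline's CSV schemas
#'
#' Plain UTF-8 comma-separated files with dot decimals. `read_ct_table`
#' validates columns, normalizes gene spellings and conditions on ingest;
#' `read_clinical` applies [validate_clinical()].
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return The data frame (readers) or `invisible(path)` (writers).
#' @name csv_io
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cohort <- simulate_cohort(sim_config(n_activators = 1,
#'                                      n_nonactivators = 1, seed = 1))
#' write_ct_table(cohort$ct_table, f)
#' identical(read_ct_table(f), validate_ct_table(cohort$ct_table))
NULL

#' @rdname csv_io
#' @export
read_ct_table <- function(path) {
  validate_ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname csv_io
#' @export
write_ct_table <- function(x, path) {
  utils::write.csv(validate_ct_table(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_clinical <- function(path) {
  validate_clinical(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname csv_io
#' @export
write_clinical <- function(x, path) {
  utils::write.csv(validate_clinical(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load the packaged 25-patient clinical fixture
#'
#' The packaged cohort transcribes the published evaluation table: 15
#' antibody-treated RA patients (golimumab, adalimumab, infliximab) and 10
#' etanercept-treated patients, each with DAS28 at baseline (M0) and month
#' 3 (M3), the assay's prediction (`+` activator, `-` non-activator, `+?`
#' uncertain) and the recorded clinical evolution (`+`/`-`). The file's
#' md5 checksum is pinned so silent drift of the fixture is an error.
#'
#' @return List with `calls` (`sample_id`, `status` -- predictions mapped
#'   onto activation statuses) and `clinical` (validated clinical table
#'   including the raw `prediction` column).
#' @examples
#' fx <- load_table2()
#' table(fx$clinical$drug_class)
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_cohort.csv", package = "tnfiRS",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, "dd7e8b69814ed9d6a4843b520ed35d1b"))
    stop("packaged fixture checksum mismatch: ", sum)
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  clin <- validate_clinical(clin)
  status <- c("+" = "Activator", "-" = "NonActivator",
              "+?" = "Uncertain")[clin$prediction]
  if (anyNA(status)) stop("unknown prediction symbol in fixture")
  list(calls = data.frame(sample_id = clin$patient_id,
                          status = unname(status),
                          stringsAsFactors = FALSE),
       clinical = clin)
}

#' Run the full analysis pipeline on raw inputs
#'
#' Composes replicate collapse, fold-change quantitation, activation
#' classification, EULAR response mapping, and concordance scoring. The
#' analysis path is fully deterministic: only the simulator consumes
#' random seeds.
#'
#' @param ct_table Raw Ct data frame (or path to its CSV).
#' @param clinical Clinical data frame (or path to its CSV). If it has no
#'   `evolution` column, one is derived from DAS28 via the EULAR grid.
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`: `profiles`, `invalid_samples`,
#'   `calls`, `clinical` (with `eular_category` and `responder` columns),
#'   and `summary` (the [concordance()] result over classifiable
#'   patients).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_activators = 3,
#'                                      n_nonactivators = 3,
#'                                      dropout_prob = 0, seed = 7))
#' rep <- run_pipeline(cohort$ct_table, cohort$clinical)
#' rep$summary$by_class
#' @export
run_pipeline <- function(ct_table, clinical, config = pipeline_config()) {
  if (is.character(ct_table)) ct_table <- read_ct_table(ct_table)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  clinical <- validate_clinical(clinical)

  prof <- build_profiles(ct_table, panel = config$gene_panel,
                         cutoff = config$non_amplified_ct_cutoff)
  calls <- classify_activation(prof$profiles, band = cv_band(config$cv))

  clinical$eular_category <- eular_response(clinical$das28_m0,
                                            clinical$das28_m3, config$grid)
  clinical$responder <- binary_response(clinical$eular_category,
                                        config$grid)
  if (!"evolution" %in% names(clinical))
    clinical$evolution <- ifelse(clinical$responder, "+", "-")

  usable <- calls[!is.na(calls$status), , drop = FALSE]
  clin_usable <- clinical[clinical$patient_id %in% usable$sample_id, ,
                          drop = FALSE]
  usable <- usable[usable$sample_id %in% clin_usable$patient_id, ,
                   drop = FALSE]
  summary <- if (nrow(usable) > 0)
    concordance(usable, clin_usable, policy = config$uncertain_policy)
  else NULL

  refused <- calls$sample_id[is.na(calls$status)]
  invalid <- prof$invalid
  if (length(refused))
    invalid <- rbind(invalid,
                     data.frame(sample_id = refused,
                                reason = "CD36 not evaluable",
                                stringsAsFactors = FALSE))

  structure(list(profiles = prof$profiles, invalid_samples = invalid,
                 calls = calls, clinical = clinical, summary = summary),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("tnfiRS pipeline report\n")
  cat("  samples classified:", sum(!is.na(x$calls$status)), "\n")
  if (nrow(x$invalid_samples))
    cat("  invalid/refused samples:",
        paste(x$invalid_samples$sample_id, collapse = ", "), "\n")
  print(table(status = x$calls$status, useNA = "ifany"))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
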