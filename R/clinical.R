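# DAS28 / EULAR response classification.

#' EULAR response grid parameters
#'
#' Cut-points of the EULAR response grid for DAS28: attained-activity
#' thresholds (low-activity endpoint 3.2, high-activity endpoint 5.1) and
#' improvement thresholds (major 1.2, minor 0.6), plus which categories
#' count as "responder" when the grid is collapsed to a binary outcome.
#' All values are configuration, not constants: published criteria vary by
#' DAS28 variant.
#'
#' @param good_endpoint_max Attained DAS28 at or below which a major
#'   improvement is a Good response (default 3.2).
#' @param moderate_endpoint_max Attained DAS28 above which a merely
#'   intermediate improvement is no response (default 5.1).
#' @param major_improvement_min Improvement (M0 - M3) that must be
#'   exceeded for a major improvement (default 1.2).
#' @param minor_improvement_min Improvement at or below which there is no
#'   response regardless of endpoint (default 0.6).
#' @param responder_set Categories mapped to "responder" by
#'   [binary_response()] (default Good and Moderate).
#' @return List of class `eular_grid`.
#' @examples
#' eular_grid()
#' @export
eular_grid <- function(good_endpoint_max = 3.2, moderate_endpoint_max = 5.1,
                       major_improvement_min = 1.2,
                       minor_improvement_min = 0.6,
                       responder_set = c("Good", "Moderate")) {
  stopifnot(minor_improvement_min < major_improvement_min,
            good_endpoint_max < moderate_endpoint_max,
            all(responder_set %in% c("Good", "Moderate")))
  structure(list(good_endpoint_max = good_endpoint_max,
                 moderate_endpoint_max = moderate_endpoint_max,
                 major_improvement_min = major_improvement_min,
                 minor_improvement_min = minor_improvement_min,
                 responder_set = responder_set),
            class = "eular_grid")
}

#' EULAR response category from baseline and follow-up DAS28
#'
#' With improvement `delta = m0 - m3`:
#' \itemize{
#'   \item `Good`: `delta > major_improvement_min` and attained
#'     `m3 <= good_endpoint_max`;
#'   \item `None`: `delta <= minor_improvement_min`, or an intermediate
#'     improvement (`minor < delta <= major`) ending above
#'     `moderate_endpoint_max`;
#'   \item `Moderate`: everything else.
#' }
#' Vectorized over `m0`/`m3`.
#'
#' @param m0,m3 DAS28 at baseline and at 3 months (non-negative, < 12).
#' @param grid An [eular_grid()].
#' @return Character vector in `c("Good", "Moderate", "None")`.
#' @examples
#' eular_response(4.50, 2.00)   # Good
#' eular_response(3.78, 4.16)   # None (worsened)
#' eular_response(6.02, 5.37)   # None (small gain, high endpoint)
#' @export
eular_response <- function(m0, m3, grid = eular_grid()) {
  if (length(m0) != length(m3)) stop("m0 and m3 must have equal length")
  if (anyNA(m0) || anyNA(m3)) stop("missing DAS28 score")
  if (any(m0 < 0 | m0 >= 12 | m3 < 0 | m3 >= 12))
    stop("DAS28 scores must be in [0, 12)")
  delta <- m0 - m3
  out <- rep("Moderate", length(m0))
  out[delta > grid$major_improvement_min & m3 <= grid$good_endpoint_max] <-
    "Good"
  out[delta <= grid$minor_improvement_min |
        (delta <= grid$major_improvement_min &
           m3 > grid$moderate_endpoint_max)] <- "None"
  out
}

#' Collapse an EULAR category to responder / non-responder
#'
#' @param category Character vector of EULAR categories.
#' @param grid An [eular_grid()]; its `responder_set` defines which
#'   categories count as response.
#' @return Logical vector: `TRUE` for responders.
#' @examples
#' binary_response(c("Good", "Moderate", "None"))
#' @export
binary_response <- function(category, grid = eular_grid()) {
  if (!all(category %in% c("Good", "Moderate", "None")))
    stop("invalid EULAR category")
  category %in% grid$responder_set
}

#' Validate a clinical record table
#'
#' Checks column presence, DAS28 ranges, and drug / drug-class
#' consistency (etanercept is the soluble receptor; adalimumab, golimumab,
#' infliximab and certolizumab are antibody-class).
#'
#' @param clinical Data frame with columns `patient_id`, `drug`,
#'   `drug_class`, `das28_m0`, `das28_m3` and optionally `evolution`
#'   (`"+"`/`"-"`).
#' @return The validated data frame (invisibly coerced types).
#' @export
validate_clinical <- function(clinical) {
  need <- c("patient_id", "drug", "drug_class", "das28_m0", "das28_m3")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  clinical$patient_id <- as.character(clinical$patient_id)
  clinical$drug <- toupper(as.character(clinical$drug))
  drug_map <- c(ADA = "antibody", GOL = "antibody", GOLI = "antibody",
                IFX = "antibody", CZP = "antibody", ETA = "soluble_receptor")
  unknown <- setdiff(clinical$drug, names(drug_map))
  if (length(unknown))
    stop("unknown drug code: ", paste(unknown, collapse = ", "))
  expected <- unname(drug_map[clinical$drug])
  if (!all(clinical$drug_class == expected))
    stop("drug_class inconsistent with drug for patient(s): ",
         paste(clinical$patient_id[clinical$drug_class != expected],
               collapse = ", "))
  for (col in c("das28_m0", "das28_m3")) {
    v <- clinical[[col]]
    if (any(is.na(v)) || any(v < 0 | v >= 12))
      stop(col, " must be non-negative and < 12")
  }
  clinical
}
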