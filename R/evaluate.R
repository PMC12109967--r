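# Prediction-vs-outcome concordance scoring.

#' Score activation-status predictions against clinical response
#'
#' Joins activation calls with clinical records by patient and counts
#' correct predictions: `Activator` predicting a responder (`"+"`
#' evolution) or `NonActivator` predicting a non-responder (`"-"`).
#' `Uncertain` calls are handled by policy:
#' \describe{
#'   \item{`exclude`}{dropped from the accuracy denominator (default);}
#'   \item{`count_wrong`}{kept in the denominator, never correct;}
#'   \item{`count_correct_if_positive`}{an uncertain-leaning-positive call
#'     counts as an `Activator` prediction (correct when the patient
#'     responded), with the full denominator.}
#' }
#' Accuracy is reported overall and per drug class.
#'
#' @param calls Data frame with `sample_id` and `status`
#'   (`Activator`/`NonActivator`/`Uncertain`), e.g. from
#'   [classify_activation()] or the packaged fixture's prediction column.
#' @param clinical Data frame with `patient_id`, `drug_class` and
#'   `evolution` (`"+"`/`"-"`); see [validate_clinical()].
#' @param policy Uncertain-call policy (see above).
#' @return List of class `evaluation_summary`: `policy`, `by_class` (one
#'   row per drug class plus `"overall"`, with `n`, `n_correct`,
#'   `n_wrong`, `n_uncertain`, `accuracy_pct`), and `confusion` (status x
#'   evolution contingency table).
#' @examples
#' fx <- load_table2()
#' concordance(fx$calls, fx$clinical)$by_class
#' @export
concordance <- function(calls, clinical,
                        policy = c("exclude", "count_wrong",
                                   "count_correct_if_positive")) {
  policy <- match.arg(policy)
  if (!all(c("sample_id", "status") %in% names(calls)))
    stop("calls must have columns sample_id and status")
  if (!all(c("patient_id", "drug_class", "evolution") %in% names(clinical)))
    stop("clinical must have columns patient_id, drug_class, evolution")
  orphan_calls <- setdiff(calls$sample_id, clinical$patient_id)
  orphan_clin  <- setdiff(clinical$patient_id, calls$sample_id)
  if (length(orphan_calls) || length(orphan_clin))
    stop("patient sets do not match; orphans: ",
         paste(c(orphan_calls, orphan_clin), collapse = ", "))
  if (!all(clinical$evolution %in% c("+", "-")))
    stop("evolution must be '+' or '-'")

  m <- merge(calls[c("sample_id", "status")],
             clinical[c("patient_id", "drug_class", "evolution")],
             by.x = "sample_id", by.y = "patient_id")
  responded <- m$evolution == "+"
  uncertain <- m$status == "Uncertain"
  correct <- (m$status == "Activator" & responded) |
             (m$status == "NonActivator" & !responded)
  if (policy == "count_correct_if_positive") {
    correct <- correct | (uncertain & responded)
    uncertain <- uncertain & !responded
  }

  # n_correct + n_wrong + n_uncertain == n always; the policy only moves
  # the accuracy denominator (and, above, resolves "+?"-style calls).
  tally <- function(idx) {
    n <- sum(idx)
    n_unc <- sum(uncertain[idx])
    n_cor <- sum(correct[idx])
    denom <- if (policy == "exclude") n - n_unc else n
    data.frame(n = n, n_correct = n_cor,
               n_wrong = n - n_cor - n_unc,
               n_uncertain = n_unc,
               accuracy_pct = if (denom > 0) 100 * n_cor / denom else NA_real_)
  }
  classes <- sort(unique(m$drug_class))
  by_class <- do.call(rbind, lapply(classes, function(cl)
    cbind(drug_class = cl, tally(m$drug_class == cl))))
  by_class <- rbind(by_class,
                    cbind(drug_class = "overall", tally(rep(TRUE, nrow(m)))))
  rownames(by_class) <- NULL

  structure(list(policy = policy, by_class = by_class,
                 confusion = table(status = m$status,
                                   evolution = m$evolution)),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("Prediction vs clinical outcome (uncertain policy: ",
      x$policy, ")\n\n", sep = "")
  print(x$by_class, row.names = FALSE)
  cat("\nConfusion (status x evolution):\n")
  print(x$confusion)
  invisible(x)
}
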