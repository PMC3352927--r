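#' @include AllClasses.R
NULL

## Controlled vocabularies of the validation tables. The human-effect ->
## acceptable-observed-category match table is transcribed from the printed
## cardiotoxicity validation rows: a QT-prolonging compound counts as detected
## only through the 2:1 atrio-ventricular arrhythmia (the zebrafish signature
## of ERG blockade), while cross-severity matches toward the stronger
## phenotype (bradycardia inducer observed as cardiac arrest) count as true
## positives.
.HUMAN_EFFECTS <- c("No effect", "Bradycardia", "QT-prolong.", "Arrhythmia",
                    "Cardiac arrest", "Angiogenesis inhibitor")
.OBSERVED_EFFECTS <- c("No effect", "Bradycardia", "Arrhythmia 2:1",
                       "Arrhythmia", "Cardiac arrest", "Inhibited",
                       "Not inhibited")
.NEGATIVE_HUMAN <- "No effect"
.NEGATIVE_OBSERVED <- c("No effect", "Not inhibited")
.MATCH_TABLE <- list(
  "Bradycardia"            = c("Bradycardia", "Cardiac arrest"),
  "QT-prolong."            = "Arrhythmia 2:1",
  "Arrhythmia"             = c("Arrhythmia", "Arrhythmia 2:1"),
  "Cardiac arrest"         = "Cardiac arrest",
  "Angiogenesis inhibitor" = "Inhibited")

#' Map a (human effect, observed effect) pair to a validation verdict
#'
#' Encodes the verdict rules of the packaged validation tables: `TN` when a
#' compound without a real effect is called negative, `FP` when it is called
#' positive, `TP` when a real effect is observed as a matching zebrafish
#' category (see Details), `FN` otherwise.
#'
#' @details The acceptable observed categories per human effect are:
#' bradycardia inducers match `Bradycardia` or `Cardiac arrest` (the stronger
#' phenotype counts as detection), QT-prolongation inducers match only
#' `Arrhythmia 2:1`, non-QT arrhythmia inducers match `Arrhythmia` (or
#' `Arrhythmia 2:1`), cardiac-arrest inducers match `Cardiac arrest`, and
#' known angiogenesis inhibitors match `Inhibited`.
#'
#' @param humanEffect label from the controlled vocabulary (see
#'   [loadValidationTable()])
#' @param observedEffect observed zebrafish category label
#' @return one of `"TP"`, `"TN"`, `"FN"`, `"FP"` (vectorised)
#' @examples
#' assignVerdict("QT-prolong.", "Arrhythmia 2:1")  # "TP"
#' assignVerdict("No effect", "No effect")         # "TN"
#' assignVerdict("QT-prolong.", "Bradycardia")     # "FN"
#' @export
assignVerdict <- function(humanEffect, observedEffect) {
  n <- max(length(humanEffect), length(observedEffect))
  humanEffect <- rep_len(as.character(humanEffect), n)
  observedEffect <- rep_len(as.character(observedEffect), n)
  bad <- !humanEffect %in% .HUMAN_EFFECTS
  if (any(bad))
    stop("unknown human-effect label(s): ",
         paste(unique(humanEffect[bad]), collapse = ", "))
  bad <- !observedEffect %in% .OBSERVED_EFFECTS
  if (any(bad))
    stop("unknown observed-effect label(s): ",
         paste(unique(observedEffect[bad]), collapse = ", "))
  vapply(seq_len(n), function(i) {
    h <- humanEffect[i]
    o <- observedEffect[i]
    if (h == .NEGATIVE_HUMAN) {
      if (o %in% .NEGATIVE_OBSERVED) "TN" else "FP"
    } else {
      if (o %in% .MATCH_TABLE[[h]]) "TP" else "FN"
    }
  }, character(1))
}

#' Load a packaged validation table
#'
#' Reads one of the CSV validation fixtures shipped with the package (or a
#' user file with the same schema) into a validation-record data frame. The
#' cardio table transcribes the 35 compounds of the cardiotoxicity screening
#' validation; the angio table the 28 compounds of the angiogenesis
#' validation.
#'
#' @param path CSV file; must contain columns `compound`, `human_effect`,
#'   `observed_effect`, `verdict` (extra columns are kept)
#' @return data.frame with one row per compound, class `"ValidationTable"`
#' @seealso [zfdata()] for the packaged fixture paths, [confusionSummary()]
#' @examples
#' tab <- loadValidationTable(zfdata("table2_cardio.csv"))
#' nrow(tab)  # 35
#' @export
loadValidationTable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  required <- c("compound", "human_effect", "observed_effect", "verdict")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("validation table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!df$verdict %in% c("TP", "TN", "FN", "FP"))
  if (length(bad))
    stop(sprintf("unknown verdict label '%s' in row %d", df$verdict[bad[1]],
                 bad[1]))
  class(df) <- c("ValidationTable", "data.frame")
  df
}

#' Load the packaged repeatability table
#'
#' Inter-assay coefficients of variation of the cardiotoxicity repeatability
#' assessment (three compounds at two concentrations, ten plates each).
#'
#' @param path CSV with columns `predominant_effect`, `compound`,
#'   `concentration_um`, `interassay_cv_pct`
#' @return data.frame
#' @export
loadRepeatabilityTable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("predominant_effect", "compound", "concentration_um",
                "interassay_cv_pct")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("repeatability table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Path to a packaged data fixture
#'
#' @param file fixture file name, e.g. `"table2_cardio.csv"`; empty to list
#'   available fixtures
#' @return full path (or a vector of file names)
#' @export
zfdata <- function(file = "") {
  if (!nzchar(file))
    return(dir(system.file("extdata", package = "zfscreen")))
  p <- system.file("extdata", file, package = "zfscreen")
  if (!nzchar(p)) stop("no packaged fixture called '", file, "'")
  p
}

#' Confusion summary of a validation table
#'
#' Counts TP/TN/FN/FP verdicts and derives the two validation rates. Note the
#' naming convention: the platform validation reports the positive-detection
#' rate `100 * TP / (TP + FN)` under the name "specificity" and the
#' correct-rejection rate `100 * TN / (TN + FP)` under the name
#' "sensitivity", which is the opposite of the conventional epidemiological
#' usage. Both labellings are therefore reported side by side. A rate with an
#' empty denominator is `NA` (undefined), not 0.
#'
#' @param records a validation-record data frame from
#'   [loadValidationTable()], or anything with a `verdict` column
#' @return a list with counts `tp`, `tn`, `fn`, `fp`, the rates
#'   `detectionRatePositives` and `correctRejectionRate` (percent), and the
#'   two naming conventions (`asPaper`, `standard`)
#' @examples
#' confusionSummary(loadValidationTable(zfdata("table2_cardio.csv")))
#' @export
confusionSummary <- function(records) {
  v <- records$verdict
  if (is.null(v)) stop("'records' must have a 'verdict' column")
  stopifnot(all(v %in% c("TP", "TN", "FN", "FP")))
  tp <- sum(v == "TP")
  tn <- sum(v == "TN")
  fn <- sum(v == "FN")
  fp <- sum(v == "FP")
  det <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  rej <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  list(tp = tp, tn = tn, fn = fn, fp = fp,
       detectionRatePositives = det,
       correctRejectionRate = rej,
       asPaper = c(specificity = det, sensitivity = rej),
       standard = c(sensitivity = det, specificity = rej),
       n = length(v))
}
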