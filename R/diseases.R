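#' Canonical chronic-disease vocabulary
#'
#' The fourteen chronic conditions tracked by the pipeline, with the short
#' machine codes used throughout the package and human-readable labels.
#' The table is also shipped as a plain-text file under
#' `inst/extdata/disease_vocabulary.csv` so external tools can consume it.
#'
#' @return A data frame with columns `code` and `label`, one row per disease.
#' @examples
#' disease_vocabulary()
#' @export
disease_vocabulary <- function() {
  path <- system.file("extdata", "disease_vocabulary.csv", package = "trajnet")
  if (nzchar(path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    # fallback used before installation (e.g. pkgload)
    data.frame(code = .diseases, label = .disease_labels,
               stringsAsFactors = FALSE)
  }
}

.diseases <- c("hypertension", "dyslipidemia", "diabetes", "cancer",
               "chronic_lung", "liver", "heart", "stroke", "kidney",
               "digestive", "emp", "mrd", "arthritis", "asthma")

.disease_labels <- c(
  "Hypertension", "Dyslipidemia", "Diabetes", "Cancer",
  "Chronic lung disease", "Liver disease", "Heart disease", "Stroke",
  "Kidney disease", "Digestive disease", "Emotional and mental problems",
  "Memory-related disease", "Arthritis", "Asthma"
)
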