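#' Published CHARLS reference tables
#'
#' Small plain-text tables of published summary statistics from the CHARLS
#' chronic-disease trajectory literature, shipped for arithmetic validation
#' of the package's reporting conventions (they are *inputs*, not outputs of
#' any computation in this package):
#'
#' * `"trajectory_top10"` — the published top-10 linear three-disease
#'   trajectories with patient counts and median inter-onset gaps (years).
#' * `"multimorbidity"` — the published weighted multimorbidity category
#'   distribution (percent of participants with 0, 1, 2, 3, 4+ of the
#'   fourteen chronic diseases).
#'
#' @param name One of `"trajectory_top10"`, `"multimorbidity"`.
#' @return A data frame.
#' @export
reference_table <- function(name = c("trajectory_top10", "multimorbidity")) {
  name <- match.arg(name)
  file <- switch(name,
    trajectory_top10 = "trajectory_top10_reference.csv",
    multimorbidity   = "multimorbidity_reference.csv"
  )
  path <- system.file("extdata", file, package = "trajnet")
  if (!nzchar(path)) {
    traj_error("trajnet_io_error",
               sprintf("reference table '%s' not found; is trajnet installed?",
                       name))
  }
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = if (name == "multimorbidity")
                    c(category = "character") else NA)
}
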