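#' Printed study summary tables
#'
#' The study's printed cohort summaries, shipped as plain CSV: the age
#' distribution of images per group and split (`"age_distribution"`),
#' and the distribution of image sizes (`"image_sizes"`). Used for
#' self-consistency checks (group totals and size counts must add up to
#' the full cohort) and for the split-fraction defaults.
#'
#' @param which `"age_distribution"` or `"image_sizes"`.
#' @return data.frame.
#' @export
studyTable <- function(which = c("age_distribution", "image_sizes")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("table_", which, ".csv"),
                      package = "ardaceph", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
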