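#' Longitudinal growth dataset
#'
#' Validates a long-format table of per-animal observations. Each record is
#' one measurement of one observable on one subject:
#' `bioluminescence` rows carry the photon flux of the proliferative
#' compartment (photons/sec), `caliper` rows the external tumor volume (cm^3).
#'
#' @param data a data frame with columns `subject`, `time` (days post-graft),
#'   `observable` (`"bioluminescence"` or `"caliper"`) and `value`.
#' @return The validated data frame, classed `"growth_data"`.
#' @export
growth_data <- function(data) {
  req <- c("subject", "time", "observable", "value")
  if (!all(req %in% names(data)))
    stop("data must have columns: ", paste(req, collapse = ", "))
  if (any(!data$observable %in% c("bioluminescence", "caliper")))
    stop("'observable' must be 'bioluminescence' or 'caliper'")
  if (any(data$time < 0)) stop("times must be non-negative (days post-graft)")
  if (any(data$value <= 0))
    stop("values must be strictly positive (multiplicative error model)")
  nb <- table(data$subject[data$observable == "bioluminescence"])
  subj <- unique(data$subject)
  if (length(nb) < length(subj) || any(nb < 2L))
    stop("every subject needs at least 2 bioluminescence records")
  out <- data[order(data$subject, data$observable, data$time),
              req, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("growth_data", "data.frame")
  out
}

#' Read a longitudinal growth dataset from CSV
#'
#' @param path CSV with columns `subject`, `time`, `observable`, `value`.
#' @return A [growth_data()] object.
#' @export
read_growth_csv <- function(path) {
  growth_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a longitudinal growth dataset to CSV
#'
#' @param data a [growth_data()] object (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

## split a growth_data into the per-subject list the SAEM engine consumes
.split_subjects <- function(data, observable = "bioluminescence") {
  d <- data[data$observable == observable, , drop = FALSE]
  lapply(split(d, factor(d$subject, levels = unique(d$subject))),
         function(s) list(id = s$subject[1], times = s$time, values = s$value))
}
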