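#' Read a recording from long-format CSV
#'
#' The interchange format is a long CSV with header
#' `channel,time_s,value`; rows may be in any order (they are restored
#' per channel by timestamp). Channel names must be among `ABP`, `ETCO2`,
#' `CBV`, `OXY`; `ABP` and `ETCO2` are required.
#'
#' @param path CSV file path.
#' @param subject_id Subject id; defaults to the file stem.
#' @param site,metadata Passed to [physio_recording()].
#' @return A [physio_recording()].
#' @export
read_recording_csv <- function(path, subject_id = NULL, site = "unknown",
                               metadata = list()) {
  subject_id <- subject_id %||% sub("\\.csv$", "", basename(path))
  df <- readr::read_csv(path, col_types = readr::cols(
    channel = readr::col_character(),
    time_s = readr::col_double(),
    value = readr::col_double()
  ))
  if (!all(c("channel", "time_s", "value") %in% names(df))) {
    abort(sprintf("%s: expected columns channel,time_s,value.", path))
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$value))
  if (length(bad)) {
    abort(sprintf("%s: non-numeric or missing value at data line(s) %s.",
                  path, toString(head(bad + 1, 5))))
  }
  unknown <- setdiff(unique(df$channel), .channels)
  if (length(unknown)) {
    abort(sprintf("%s: unknown channel(s) %s.", path, toString(unknown)))
  }
  channels <- lapply(split(df, df$channel), function(ch) {
    ch <- ch[order(ch$time_s), ]
    if (any(diff(ch$time_s) <= 0)) {
      abort(sprintf("%s: duplicate timestamps in channel %s.",
                    path, ch$channel[1]))
    }
    tibble::tibble(time_s = ch$time_s, value = ch$value)
  })
  dur <- max(df$time_s) - min(df$time_s)
  physio_recording(subject_id, channels, duration_s = dur, site = site,
                   metadata = metadata)
}

#' Write a recording to long-format CSV
#' @param recording A [physio_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "physio_recording"))
  readr::write_csv(
    tibble::tibble(channel = recording$channel, time_s = recording$time_s,
                   value = recording$value),
    path
  )
  invisible(path)
}

#' Write / read a fitted kernel model as a JSON bundle
#'
#' The bundle stores `{alpha, L, M, Ts, k0, c_ABP, c_CO2, k_ABP, k_CO2,
#' nmse}` and round-trips losslessly to working precision.
#'
#' @param model A [fit_kernel_model()] result.
#' @param path JSON path.
#' @return `path` (write) or a `kernel_model`-like list (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "kernel_model"))
  jsonlite::write_json(
    list(output = model$output, alpha = model$basis$alpha, L = model$basis$L,
         M = model$basis$M, Ts = model$Ts, k0 = model$k0,
         c_ABP = model$c_abp, c_CO2 = model$c_co2,
         k_ABP = model$k_abp, k_CO2 = model$k_co2, nmse = model$nmse),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- laguerre_basis(x$alpha, x$L, x$M)
  structure(
    list(output = x$output, k0 = x$k0, c_abp = x$c_ABP, c_co2 = x$c_CO2,
         k_abp = x$k_ABP, k_co2 = x$k_CO2, basis = basis, Ts = x$Ts,
         nmse = x$nmse),
    class = "kernel_model"
  )
}

#' Read / write the cohort table CSV
#'
#' One row per subject: diagnosis, covariates and neuroimaging outcomes
#' (plus any `true_*` ground-truth columns for synthetic cohorts).
#'
#' @param path CSV path.
#' @return Tibble (read) or `path` (write).
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!"subject_id" %in% names(df)) {
    abort(sprintf("%s: cohort table must have a subject_id column.", path))
  }
  if ("diagnosis" %in% names(df)) {
    df$diagnosis <- factor(df$diagnosis, levels = c("CN", "MCI", "dementia"))
  }
  df
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
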