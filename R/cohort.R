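#' Recognised tumour stage codes
#'
#' The stage labels that may appear in a cohort: AJCC substages observed in
#' the study population plus `"Mucosal"` for mucosal-primary lesions and
#' `"Unknown"`. Any other string is rejected during validation rather than
#' coerced.
#'
#' @return character vector of the eleven valid stage labels.
#' @export
stage_levels <- function() {
  c("1A", "1B", "2A", "2B", "2C", "3", "3A", "3B", "3C", "Mucosal", "Unknown")
}

#' Construct a patient cohort
#'
#' A cohort couples a per-patient summary table with an optional long-format
#' table of serial blood-draw measurements. Each patient carries a stage
#' code, the lowest and highest CMC count per ml observed over their samples,
#' a metastasis flag, and an event day: days from the time origin (initial
#' surgical excision) to metastasis diagnosis if they progressed, otherwise
#' to their last assayed sample.
#'
#' When per-sample rows are supplied their per-patient min/max must agree
#' with the stored lowest/highest summaries, and no sample may postdate the
#' event day; both are checked by [validate_cohort()].
#'
#' @param patients data.frame with columns `patient_id`, `stage`,
#'   `lowest_cmc`, `highest_cmc`, `metastasis` (logical or "Yes"/"No"),
#'   `event_day`.
#' @param samples optional data.frame with columns `patient_id`, `day`,
#'   `cmc_count` (long format, one row per blood draw).
#' @param metadata character, free-form provenance notes.
#' @return an object of class `cmc_cohort`.
#' @seealso [load_cohort()], [bundled_study_cohort()]
#' @export
new_cohort <- function(patients, samples = NULL, metadata = character()) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  if (is.character(patients$metastasis)) {
    patients$metastasis <- parse_metastasis(patients$metastasis)
  }
  if (is.null(samples)) {
    samples <- data.frame(patient_id = character(), day = integer(),
                          cmc_count = integer())
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  obj <- structure(
    list(patients = patients, samples = samples, metadata = metadata),
    class = "cmc_cohort"
  )
  validate_cohort(obj)
}

parse_metastasis <- function(x) {
  lx <- tolower(trimws(x))
  ok <- lx %in% c("yes", "no")
  if (!all(ok)) {
    stop_cmc(sprintf("metastasis must be Yes/No; got %s at row %d",
                     dQuote(x[!ok][1]), which(!ok)[1]),
             "cmcflow_validation_error")
  }
  lx == "yes"
}

#' Validate a cohort object
#'
#' Checks the cohort invariants: required columns, unique patient ids, stage
#' codes drawn from [stage_levels()], non-negative integer counts and days,
#' `lowest_cmc <= highest_cmc`, and — when long-format samples are present —
#' agreement between the per-sample min/max and the stored summaries, and
#' `event_day >= max(day)`.
#'
#' @param cohort a `cmc_cohort`.
#' @return the cohort, invisibly unchanged, if valid; otherwise an error of
#'   class `cmcflow_validation_error` (or `cmcflow_schema_error` for missing
#'   columns) describing the first violation found.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients
  need <- c("patient_id", "stage", "lowest_cmc", "highest_cmc",
            "metastasis", "event_day")
  missing_col <- setdiff(need, names(p))
  if (length(missing_col)) {
    stop_cmc(paste0("cohort is missing column(s): ",
                    paste(missing_col, collapse = ", ")),
             "cmcflow_schema_error")
  }
  if (anyDuplicated(p$patient_id)) {
    stop_cmc("patient_id values must be unique", "cmcflow_validation_error")
  }
  bad_stage <- !(p$stage %in% stage_levels())
  if (any(bad_stage)) {
    stop_cmc(sprintf("unrecognised stage %s at row %d",
                     dQuote(p$stage[bad_stage][1]), which(bad_stage)[1]),
             "cmcflow_validation_error")
  }
  for (col in c("lowest_cmc", "highest_cmc", "event_day")) {
    if (nrow(p) && !is_count(p[[col]])) {
      bad <- which(!(is.finite(p[[col]]) & p[[col]] >= 0 &
                       p[[col]] == floor(p[[col]])))[1]
      stop_cmc(sprintf("column %s must be a non-negative integer; row %d",
                       col, bad), "cmcflow_validation_error")
    }
  }
  if (any(p$lowest_cmc > p$highest_cmc)) {
    stop_cmc("lowest_cmc exceeds highest_cmc", "cmcflow_validation_error")
  }
  if (!is.logical(p$metastasis) || anyNA(p$metastasis)) {
    stop_cmc("metastasis must be logical (or Yes/No strings)",
             "cmcflow_validation_error")
  }
  s <- cohort$samples
  if (nrow(s)) {
    need_s <- c("patient_id", "day", "cmc_count")
    miss_s <- setdiff(need_s, names(s))
    if (length(miss_s)) {
      stop_cmc(paste0("samples table is missing column(s): ",
                      paste(miss_s, collapse = ", ")), "cmcflow_schema_error")
    }
    if (!is_count(s$day) || !is_count(s$cmc_count)) {
      stop_cmc("sample day and cmc_count must be non-negative integers",
               "cmcflow_validation_error")
    }
    orphan <- !(s$patient_id %in% p$patient_id)
    if (any(orphan)) {
      stop_cmc(sprintf("sample row %d refers to unknown patient %s",
                       which(orphan)[1], dQuote(s$patient_id[orphan][1])),
               "cmcflow_validation_error")
    }
    mn <- tapply(s$cmc_count, s$patient_id, min)
    mx <- tapply(s$cmc_count, s$patient_id, max)
    last_day <- tapply(s$day, s$patient_id, max)
    idx <- match(names(mn), p$patient_id)
    bad <- which(mn != p$lowest_cmc[idx] | mx != p$highest_cmc[idx])
    if (length(bad)) {
      b <- bad[1]
      stop_cmc(sprintf(
        "patient %s: sample min/max (%d/%d) disagree with stored summary (%d/%d)",
        names(mn)[b], mn[b], mx[b], p$lowest_cmc[idx[b]], p$highest_cmc[idx[b]]),
        "cmcflow_validation_error")
    }
    late <- which(p$event_day[idx] < last_day)
    if (length(late)) {
      stop_cmc(sprintf("patient %s: event_day precedes last sample day",
                       names(mn)[late[1]]), "cmcflow_validation_error")
    }
  }
  invisible(cohort)
}

#' @export
print.cmc_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  cat(sprintf("<cmc_cohort> %d patient%s, %d metastatic; %d sample rows\n",
              n, if (n == 1) "" else "s", sum(x$patients$metastasis),
              nrow(x$samples)))
  if (length(x$metadata)) cat(" ", paste(x$metadata, collapse = "; "), "\n")
  invisible(x)
}

#' Read a cohort from CSV or JSON
#'
#' CSV input is a comma-delimited table with a header row and the per-patient
#' summary columns; per-sample rows may be supplied through `samples_file`.
#' JSON input is a single object with a `patients` array (each element may
#' carry a `samples` array of `{day, cmc_count}`) and optional `metadata`.
#' Reading then [write_cohort()] then reading again is lossless.
#'
#' @param file path to the cohort file.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @param samples_file optional path to a long-format CSV of per-sample rows
#'   (`patient_id`, `day`, `cmc_count`); CSV format only.
#' @return a validated `cmc_cohort`.
#' @export
load_cohort <- function(file, format = c("auto", "csv", "json"),
                        samples_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", file, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    p <- utils::read.csv(file, stringsAsFactors = FALSE)
    if ("patient_id" %in% names(p)) p$patient_id <- as.character(p$patient_id)
    s <- NULL
    if (!is.null(samples_file)) {
      s <- utils::read.csv(samples_file, stringsAsFactors = FALSE)
      s$patient_id <- as.character(s$patient_id)
    }
    new_cohort(p, s, metadata = sprintf("loaded from %s", basename(file)))
  } else {
    obj <- jsonlite::read_json(file, simplifyVector = FALSE)
    pats <- obj$patients
    p <- do.call(rbind, lapply(pats, function(q) {
      data.frame(patient_id = as.character(q$patient_id),
                 stage = q$stage,
                 lowest_cmc = q$lowest_cmc, highest_cmc = q$highest_cmc,
                 metastasis = q$metastasis, event_day = q$event_day,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(p)) {
      p <- data.frame(patient_id = character(), stage = character(),
                      lowest_cmc = integer(), highest_cmc = integer(),
                      metastasis = logical(), event_day = integer())
    }
    s <- do.call(rbind, lapply(pats, function(q) {
      if (is.null(q$samples) || !length(q$samples)) return(NULL)
      data.frame(patient_id = as.character(q$patient_id),
                 day = vapply(q$samples, `[[`, 0, "day"),
                 cmc_count = vapply(q$samples, `[[`, 0, "cmc_count"),
                 stringsAsFactors = FALSE)
    }))
    md <- if (is.null(obj$metadata)) character() else unlist(obj$metadata)
    new_cohort(p, s, metadata = md)
  }
}

#' Write a cohort to CSV or JSON
#'
#' @param cohort a `cmc_cohort`.
#' @param file output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @param samples_file optional path for the long-format sample rows (CSV
#'   format only); required if the cohort carries samples and format is CSV.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file, format = c("auto", "csv", "json"),
                         samples_file = NULL) {
  validate_cohort(cohort)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", file, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    p <- cohort$patients
    p$metastasis <- ifelse(p$metastasis, "Yes", "No")
    utils::write.csv(p, file, row.names = FALSE, quote = FALSE)
    if (nrow(cohort$samples)) {
      if (is.null(samples_file)) {
        stop_cmc("cohort has sample rows; supply samples_file for CSV output",
                 "cmcflow_io_error")
      }
      utils::write.csv(cohort$samples, samples_file, row.names = FALSE,
                       quote = FALSE)
    }
  } else {
    pats <- lapply(seq_len(nrow(cohort$patients)), function(i) {
      row <- cohort$patients[i, ]
      out <- list(patient_id = row$patient_id, stage = row$stage,
                  lowest_cmc = row$lowest_cmc, highest_cmc = row$highest_cmc,
                  metastasis = row$metastasis, event_day = row$event_day)
      ss <- cohort$samples[cohort$samples$patient_id == row$patient_id, ]
      if (nrow(ss)) {
        out$samples <- lapply(seq_len(nrow(ss)), function(j) {
          list(day = ss$day[j], cmc_count = ss$cmc_count[j])
        })
      }
      out
    })
    jsonlite::write_json(list(patients = pats,
                              metadata = as.list(cohort$metadata)),
                         file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

.fixture_md5 <- c(
  study_cohort.csv      = "2d0f8906cf5ab7ceb0a2edd661103204",
  study_contingency.csv = "6a37a343eb95d7b95faaf3947b2c6b9c"
)

check_fixture <- function(path, name) {
  if (!nzchar(path) || !file.exists(path)) {
    stop_cmc(sprintf("bundled fixture %s not found", name),
             "cmcflow_integrity_error")
  }
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]]))) {
    stop_cmc(sprintf("bundled fixture %s failed its integrity check", name),
             "cmcflow_integrity_error")
  }
  path
}

fixture_path <- function(name) {
  check_fixture(system.file("extdata", name, package = "cmcflow"), name)
}

#' The bundled 38-patient study cohort
#'
#' Returns the published cohort: 11 patients whose CMC count never exceeded
#' 2/ml (none metastatic), 17 printed rows of patients exceeding 2 CMCs/ml
#' who progressed to metastasis, and 10 who exceeded 2 CMCs/ml without
#' progressing. Only lowest/highest per-patient summaries are available, so
#' the samples table is empty. The fixture is checksummed; a corrupted file
#' raises an integrity error.
#'
#' Note the known discrepancy: the printed per-patient tables contain 17
#' metastatic rows while the published 2x2 contingency counts (and the
#' accompanying text) report 18 metastatic of 27 in the high group. One
#' metastatic row is evidently missing from the printed tables. Analyses
#' that reproduce the published aggregate percentages should use
#' [study_contingency_counts()]; see [reproduce_paper()], which surfaces the
#' discrepancy explicitly.
#'
#' @return a validated `cmc_cohort` with 38 patients.
#' @export
bundled_study_cohort <- function() {
  co <- load_cohort(fixture_path("study_cohort.csv"), format = "csv")
  co$metadata <- "bundled study cohort (38 patients, summary-only)"
  co
}

#' The published 2x2 contingency counts
#'
#' The metastasis-by-threshold-group counts as published: 0 and 18 metastatic
#' in the low (<=2 CMCs/ml always) and high (>2 CMCs/ml ever) groups, 11 and
#' 9 non-metastatic. These counts are shipped separately from the per-patient
#' tables because the printed tables contain one fewer metastatic row (17)
#' than these counts; see [bundled_study_cohort()].
#'
#' @return a `cmc_contingency` object (see [contingency()]).
#' @export
study_contingency_counts <- function() {
  tab <- utils::read.csv(fixture_path("study_contingency.csv"),
                         stringsAsFactors = FALSE)
  contingency_from_counts(a = tab$low_group[tab$metastasis == "Yes"],
                          b = tab$high_group[tab$metastasis == "Yes"],
                          c = tab$low_group[tab$metastasis == "No"],
                          d = tab$high_group[tab$metastasis == "No"])
}

#' Per-patient maximum CMC count
#'
#' The highest CMC count per ml observed for each patient, taken over the
#' long-format samples when present and otherwise from the stored
#' `highest_cmc` summary. All threshold classification in this package
#' consumes only this maximum, so summary-only and full-series cohorts
#' behave identically.
#'
#' @param cohort a `cmc_cohort`.
#' @param patient_id optional single id; default all patients.
#' @return named integer vector of per-patient maxima.
#' @export
patient_max_cmc <- function(cohort, patient_id = NULL) {
  p <- cohort$patients
  if (!is.null(patient_id)) {
    p <- p[p$patient_id %in% patient_id, , drop = FALSE]
    if (!nrow(p)) {
      stop_cmc(sprintf("no patient with id %s", dQuote(patient_id)),
               "cmcflow_empty_record_error")
    }
  }
  if (!nrow(p)) {
    stop_cmc("cohort has no patients", "cmcflow_empty_record_error")
  }
  out <- p$highest_cmc
  s <- cohort$samples
  if (nrow(s)) {
    mx <- tapply(s$cmc_count, s$patient_id, max)
    hit <- p$patient_id %in% names(mx)
    out[hit] <- as.integer(mx[p$patient_id[hit]])
  }
  stats::setNames(as.integer(out), p$patient_id)
}
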