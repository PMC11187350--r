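#' Cohort table schema
#'
#' A cohort is a plain `data.frame` with one row per patient and columns
#' `patient_id`, `age`, `sex`, `diagnosis`, `los`, `used_herb`, and two
#' list-columns `admission_symptoms` and `relieved_symptoms` holding
#' character vectors of lower-cased symptom terms. The invariant
#' `relieved_symptoms` is a subset of `admission_symptoms` holds for every row: a
#' symptom can only be recorded as relieved at discharge if it was present
#' at admission.
#'
#' @name cohort-schema
#' @keywords internal
NULL

cohort_required_cols <- c("patient_id", "age", "sex", "diagnosis", "los",
                          "used_herb", "admission_symptoms",
                          "relieved_symptoms")

split_terms <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         normalize_terms)
}

#' Assemble and validate a cohort data frame
#'
#' Normalizes symptom terms, enforces the relieved-within-admission
#' invariant by intersection (counting repairs), and validates age/LOS.
#'
#' @param df data.frame with the columns of [cohort-schema]; the symptom
#'   columns may be `;`-delimited strings or list-columns.
#' @return validated cohort data.frame; attribute `load_report` holds
#'   `n_records` and `n_repaired`.
#' @export
as_cohort <- function(df) {
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols)) {
    stop_input("cohort schema error: missing column(s) ",
               paste(missing_cols, collapse = ", "))
  }
  out <- df[cohort_required_cols]
  out$patient_id <- as.character(out$patient_id)
  for (col in c("age", "los")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad)) {
      stop_input("cohort parse error: non-numeric ", col,
                 " in row ", bad[1L])
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop_input("cohort validation error: negative ", col,
                 " in row ", neg[1L])
    }
    out[[col]] <- v
  }
  out$sex <- tolower(as.character(out$sex))
  ok_sex <- out$sex %in% c("male", "female")
  if (!all(ok_sex)) {
    stop_input("cohort validation error: sex must be male/female (row ",
               which(!ok_sex)[1L], ")")
  }
  out$diagnosis <- as.character(out$diagnosis)
  uh <- out$used_herb
  if (!is.logical(uh)) uh <- as.integer(as.character(uh)) == 1L
  if (anyNA(uh)) {
    stop_input("cohort parse error: used_herb must be 0/1 (row ",
               which(is.na(uh))[1L], ")")
  }
  out$used_herb <- uh
  for (col in c("admission_symptoms", "relieved_symptoms")) {
    if (is.list(df[[col]])) {
      v <- df[[col]]
      nonempty <- lengths(v) > 0L
      v[nonempty] <- lapply(v[nonempty], normalize_terms)
      out[[col]] <- v
    } else {
      out[[col]] <- split_terms(as.character(df[[col]]))
    }
  }
  repaired <- logical(nrow(out))
  check <- which(lengths(out$relieved_symptoms) > 0L)
  for (i in check) {
    extra <- setdiff(out$relieved_symptoms[[i]], out$admission_symptoms[[i]])
    if (length(extra)) {
      repaired[i] <- TRUE
      out$relieved_symptoms[[i]] <-
        intersect(out$relieved_symptoms[[i]], out$admission_symptoms[[i]])
    }
  }
  rownames(out) <- NULL
  attr(out, "load_report") <- list(n_records = nrow(out),
                                   n_repaired = sum(repaired))
  out
}

#' Read a patient cohort from CSV
#'
#' Expects a header with `patient_id, age, sex, diagnosis, los, used_herb,
#' admission_symptoms, relieved_symptoms`; symptom sets are
#' semicolon-delimited strings, `used_herb` is 0/1. Records whose relieved
#' set is not contained in the admission set are repaired by intersection
#' and counted in the load report.
#'
#' @param path path to the CSV file.
#' @return a cohort data.frame (see [cohort-schema]).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop_input("cohort file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_cohort(df)
}

#' Write a cohort to CSV
#'
#' Symptom list-columns are joined with `;` so the file round-trips through
#' [read_cohort_csv()].
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  out$used_herb <- as.integer(out$used_herb)
  out$admission_symptoms <- vapply(cohort$admission_symptoms,
                                   paste, "", collapse = ";")
  out$relieved_symptoms <- vapply(cohort$relieved_symptoms,
                                  paste, "", collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
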