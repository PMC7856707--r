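#' @name registry_schemas
#' @title Registry file schemas
#' @description
#' Both registries are flat CSV tables with fixed headers and ISO-8601
#' (YYYY-MM-DD) dates. Empty cells denote missing values.
#'
#' Surgery registry columns: `record_id, surname, forename, mrn, dob, sex,
#' procedure_date, hosp_adm_date, hosp_dis_date, icu_dis_date, age, urgency,
#' procedure_type, risk_of_death`. `icu_dis_date` is the discharge date of
#' the post-operative ICU stay as recorded by the surgical registry (empty
#' when there was no post-operative ICU episode); both source registries
#' record ICU as well as hospital admission and discharge dates, which is
#' what makes the staged date-matching plans possible.
#'
#' ICU registry columns: `record_id, surname, forename, mrn, dob, sex, slk,
#' icu_adm_date, icu_dis_date, hosp_adm_date, hosp_dis_date, age`. Identity
#' fields may be empty (the deidentified registry retains SLK-581 even when
#' names and MRN are missing).
#'
#' Sex is serialized as `M`/`F`/`U`; ages are integer years;
#' `risk_of_death` is a fraction in \[0, 1\].
NULL

surgery_columns <- c("record_id", "surname", "forename", "mrn", "dob", "sex",
                     "procedure_date", "hosp_adm_date", "hosp_dis_date",
                     "icu_dis_date", "age", "urgency", "procedure_type",
                     "risk_of_death")

icu_columns <- c("record_id", "surname", "forename", "mrn", "dob", "sex",
                 "slk", "icu_adm_date", "icu_dis_date", "hosp_adm_date",
                 "hosp_dis_date", "age")

date_columns <- list(
  surgery = c("dob", "procedure_date", "hosp_adm_date", "hosp_dis_date",
              "icu_dis_date"),
  icu = c("dob", "icu_adm_date", "icu_dis_date", "hosp_adm_date",
          "hosp_dis_date")
)

# Parse an ISO-8601 date column strictly; empty cells become NA, any
# non-empty cell that is not a valid calendar date is an error naming rows.
parse_date_col <- function(x, col) {
  x <- trimws(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(x != "" & is.na(d))
  if (length(bad)) {
    stop(sprintf("invalid date(s) in column '%s' at row(s) %s: %s",
                 col, paste(bad, collapse = ", "),
                 paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  d
}

#' Read a registry CSV
#'
#' Reads and validates one registry table (see [registry_schemas] for the
#' column layout). Dates are parsed strictly as ISO-8601 calendar dates and
#' malformed cells are reported with their row numbers; a missing required
#' column is a schema error and a duplicated `record_id` an integrity error.
#'
#' @param path Path to the CSV file.
#' @param schema `"surgery"` or `"icu"`.
#' @return A `data.frame` (classed `surgery_registry` or `icu_registry`)
#'   with `Date` date columns, integer `age`, and character identity fields
#'   where empty strings denote missing values.
#' @export
read_registry <- function(path, schema = c("surgery", "icu")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  want <- if (schema == "surgery") surgery_columns else icu_columns
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: %s registry is missing column(s): %s",
                 schema, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[want]
  if (anyDuplicated(df$record_id)) {
    dup <- unique(df$record_id[duplicated(df$record_id)])
    stop("integrity error: duplicate record_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in date_columns[[schema]]) df[[col]] <- parse_date_col(df[[col]], col)
  df$age <- as.integer(df$age)
  if (schema == "surgery") {
    df$risk_of_death <- as.numeric(df$risk_of_death)
  }
  class(df) <- c(paste0(schema, "_registry"), "data.frame")
  df
}

#' Write a registry CSV
#'
#' Inverse of [read_registry()]: dates are serialized as ISO-8601 and
#' missing values as empty cells, so `read_registry(write_registry(x))`
#' round-trips field for field.
#'
#' @param registry Registry data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  out <- as.data.frame(registry)
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

default_weights <- function() {
  list(surname  = c(agree = 7,  disagree = -3),
       forename = c(agree = 5,  disagree = -2),
       mrn      = c(agree = 15, disagree = -5),
       slk      = c(agree = 10, disagree = -2),
       date     = c(agree = 2,  disagree = -40))
}

#' Linkage configuration
#'
#' Bundles the tunable parameters shared by the linkage strategies. The
#' defaults are the study values: agreement/disagreement weights of 7/-3
#' (surname), 5/-2 (forename), 15/-5 (MRN), 10/-2 (SLK-581) and 2/-40
#' (procedure date vs ICU admission date), a two-sided date caliper of 2
#' days, a total-score cutoff of 1, and staged-matching tolerances of
#' \eqn{\pm}2 days for dates and \eqn{\pm}2 years for age.
#'
#' @param fields Character vector naming the fields the probabilistic score
#'   sums over, a subset of `c("surname", "forename", "mrn", "slk", "date")`.
#' @param weights Named list of `c(agree, disagree)` pairs; every configured
#'   field must satisfy `agree > 0 > disagree`.
#' @param caliper_days Two-sided caliper (days) on |ICU admission date −
#'   procedure date| inside which the date field agrees.
#' @param cutoff Minimum total score for a candidate pair to be acceptable.
#' @param date_tolerance_days,age_tolerance_years Loosened-stage tolerances
#'   for the deterministic plans.
#' @return An object of class `link_config`.
#' @export
link_config <- function(fields = c("surname", "forename", "mrn", "slk", "date"),
                        weights = default_weights(),
                        caliper_days = 2L,
                        cutoff = 1,
                        date_tolerance_days = 2L,
                        age_tolerance_years = 2L) {
  known <- names(default_weights())
  bad <- setdiff(fields, known)
  if (length(bad)) stop("unknown field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  w <- default_weights()
  w[names(weights)] <- weights
  for (f in fields) {
    if (!(w[[f]][["agree"]] > 0 && w[[f]][["disagree"]] < 0)) {
      stop(sprintf(
        "invalid weights for '%s': agree weight must be > 0 and disagree weight < 0",
        f), call. = FALSE)
    }
  }
  if (caliper_days < 0 || date_tolerance_days < 0 || age_tolerance_years < 0) {
    stop("calipers and tolerances must be non-negative", call. = FALSE)
  }
  structure(list(fields = fields, weights = w,
                 caliper_days = as.integer(caliper_days),
                 cutoff = cutoff,
                 date_tolerance_days = as.integer(date_tolerance_days),
                 age_tolerance_years = as.integer(age_tolerance_years)),
            class = "link_config")
}

#' Load a linkage configuration from a key/value file
#'
#' The file is plain text, one `key = value` per line; `#` starts a
#' comment. Recognized keys: `fields` (comma-separated list),
#' `<field>_agree` and `<field>_disagree` for each scored field, `cutoff`,
#' `caliper_days`, `date_tolerance_days`, `age_tolerance_years`. Any key
#' left unspecified takes the shipped default, so an empty file yields the
#' default [link_config()].
#'
#' @param path Path to the configuration file.
#' @return A `link_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln, call. = FALSE)
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  args <- list()
  if (!is.null(kv$fields)) {
    args$fields <- trimws(strsplit(kv$fields, ",")[[1]])
    kv$fields <- NULL
  }
  w <- default_weights()
  scalar_keys <- c("cutoff", "caliper_days", "date_tolerance_days",
                   "age_tolerance_years")
  for (key in names(kv)) {
    val <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(val)) stop("non-numeric value for key '", key, "'", call. = FALSE)
    if (key %in% scalar_keys) {
      args[[key]] <- val
    } else if (grepl("_(agree|disagree)$", key)) {
      f <- sub("_(agree|disagree)$", "", key)
      side <- sub(sprintf("^%s_", f), "", key)
      if (!f %in% names(w)) stop("unknown field in key '", key, "'", call. = FALSE)
      w[[f]][[side]] <- val
    } else {
      stop("unknown config key: ", key, call. = FALSE)
    }
  }
  args$weights <- w
  do.call(link_config, args)
}

#' @export
print.link_config <- function(x, ...) {
  cat("Linkage configuration\n")
  cat("  scored fields:", paste(x$fields, collapse = ", "), "\n")
  for (f in x$fields) {
    cat(sprintf("    %-8s agree %+g / disagree %+g\n",
                f, x$weights[[f]][["agree"]], x$weights[[f]][["disagree"]]))
  }
  cat(sprintf("  date caliper: %d days, cutoff: %g\n", x$caliper_days, x$cutoff))
  cat(sprintf("  staged tolerances: +/-%d days, +/-%d years\n",
              x$date_tolerance_days, x$age_tolerance_years))
  invisible(x)
}
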