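#' Controlled species vocabulary
#'
#' The six *Azolla* species labels accepted throughout the package. Growth
#' records carrying any other species label are rejected at validation.
#'
#' @return Character vector of the six controlled labels.
#' @export
azolla_species <- function() {
  c("A_pinnata", "A_filiculoides", "A_caroliniana",
    "A_mexicana", "A_microphylla", "A_nilotica")
}

#' Relative growth rate from an initial/final mass pair
#'
#' Computes the per-day relative growth rate (RGR) from biomass measured at
#' the start and end of a growth period: `ln(mass_final / mass_initial) /
#' duration`, in g g^-1 d^-1. This is the standard exponential-growth
#' definition; negative values indicate biomass loss.
#'
#' @param mass_initial Biomass at the start of the period, grams (> 0).
#' @param mass_final Biomass at the end of the period, grams (> 0).
#' @param duration Length of the growth period, days (> 0).
#' @return RGR in per day; vectorized over its arguments.
#' @examples
#' rgr_from_masses(1, exp(1), 1)    # 1 d^-1
#' rgr_from_masses(0.5, 2, 7)       # ln(4)/7
#' @export
rgr_from_masses <- function(mass_initial, mass_final, duration) {
  check_positive(mass_initial, "mass_initial")
  check_positive(mass_final, "mass_final")
  check_positive(duration, "duration")
  log(mass_final / mass_initial) / duration
}

#' Relative growth rate from a doubling time
#'
#' Inverts the doubling-time relation `DT = ln(2) / RGR`, returning
#' `ln(2) / doubling_time` in per day. Round-trips with
#' [doubling_time_from_rgr()] to machine precision.
#'
#' @param doubling_time Time for the population to double, days (> 0).
#' @return RGR in per day; vectorized.
#' @export
rgr_from_doubling_time <- function(doubling_time) {
  check_positive(doubling_time, "doubling_time")
  log(2) / doubling_time
}

#' @rdname rgr_from_doubling_time
#' @param rgr Relative growth rate, per day (> 0).
#' @export
doubling_time_from_rgr <- function(rgr) {
  check_positive(rgr, "rgr")
  log(2) / rgr
}

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Harmonize raw literature growth records
#'
#' Literature studies report growth in heterogeneous ways: RGR directly, an
#' initial/final mass pair over a period, or a doubling time. This function
#' reduces every raw row to a single `(study, species, temperature, rgr)`
#' observation, filling `rgr` with precedence
#' reported > from masses > from doubling time, and records which path fired
#' in `rgr_source`. Rows with no usable growth information, an unknown
#' species, or a non-finite temperature are rejected and logged, never
#' silently dropped.
#'
#' Temperature entries given as a range (`"20-30"`) or a day/night pair
#' (`"30/20"`) are reduced to their arithmetic mean; the original text is
#' preserved in `conditions`.
#'
#' @param raw A data frame of raw records. Recognized columns:
#'   `study_id`, `species`, `strain`, `temperature`, `rgr`, `sd`,
#'   `conditions`, `mass_initial`, `mass_final`, `time_initial`,
#'   `time_final`, `doubling_time`. Missing columns are treated as all-`NA`.
#' @param keep_manipulated Keep records flagged with additional environmental
#'   manipulations (CO2, pH, phosphorus, light) in `conditions`; default
#'   `TRUE`.
#' @return A `record_table`: a tibble with columns `study_id`, `species`,
#'   `strain`, `temperature`, `rgr`, `rgr_source`, `sd`, `conditions`, plus a
#'   `"filter_log"` attribute describing rejected rows.
#' @export
harmonize_records <- function(raw, keep_manipulated = TRUE) {
  raw <- tibble::as_tibble(raw)
  n <- nrow(raw)
  col <- function(name, default = NA_real_) {
    if (name %in% names(raw)) raw[[name]] else rep(default, n)
  }
  study_id <- as.character(col("study_id", NA_character_))
  study_id[is.na(study_id)] <- paste0("study_", which(is.na(study_id)))
  species  <- as.character(col("species", NA_character_))
  strain   <- as.character(col("strain", NA_character_))
  cond     <- as.character(col("conditions", NA_character_))

  temp_parsed <- parse_temperature(col("temperature", NA))
  temperature <- temp_parsed$value
  cond <- ifelse(is.na(temp_parsed$original), cond,
                 paste_conditions(cond, temp_parsed$original))

  rgr_rep <- as.numeric(col("rgr"))
  sdv     <- as.numeric(col("sd"))
  m1 <- as.numeric(col("mass_initial"))
  m2 <- as.numeric(col("mass_final"))
  t1 <- as.numeric(col("time_initial"))
  t2 <- as.numeric(col("time_final"))
  dt <- as.numeric(col("doubling_time"))
  duration <- t2 - t1

  rgr <- rep(NA_real_, n)
  src <- rep(NA_character_, n)
  reject <- character(n)

  for (i in seq_len(n)) {
    if (is.finite(rgr_rep[i])) {
      rgr[i] <- rgr_rep[i]; src[i] <- "reported"
    } else if (is.finite(m1[i]) && is.finite(m2[i]) && is.finite(duration[i])) {
      if (m1[i] <= 0 || m2[i] <= 0 || duration[i] <= 0) {
        reject[i] <- "non-positive mass or duration"
      } else {
        rgr[i] <- rgr_from_masses(m1[i], m2[i], duration[i])
        src[i] <- "from_masses"
      }
    } else if (is.finite(dt[i])) {
      if (dt[i] <= 0) {
        reject[i] <- "non-positive doubling time"
      } else {
        rgr[i] <- rgr_from_doubling_time(dt[i])
        src[i] <- "from_doubling_time"
      }
    } else {
      reject[i] <- "no usable growth information"
    }
    if (reject[i] == "") {
      if (!is.finite(temperature[i])) reject[i] <- "missing or unparseable temperature"
      else if (is.na(species[i]) || !species[i] %in% azolla_species())
        reject[i] <- "species not in controlled vocabulary"
      else if (!is.finite(rgr[i])) reject[i] <- "non-finite rgr"
    }
  }

  manipulated <- !is.na(cond) &
    grepl("co2|\\bph\\b|phosph|light", cond, ignore.case = TRUE)
  if (!keep_manipulated) {
    reject[reject == "" & manipulated] <- "extra environmental manipulation"
  }

  keep <- reject == ""
  out <- tibble::tibble(
    study_id = study_id[keep], species = species[keep], strain = strain[keep],
    temperature = temperature[keep], rgr = rgr[keep], rgr_source = src[keep],
    sd = sdv[keep], conditions = cond[keep]
  )
  log <- tibble::tibble(row = which(!keep), reason = reject[!keep])
  new_record_table(out, filter_log = log)
}

parse_temperature <- function(x) {
  if (is.numeric(x)) return(list(value = as.numeric(x), original = rep(NA_character_, length(x))))
  x <- as.character(x)
  value <- suppressWarnings(as.numeric(x))
  original <- rep(NA_character_, length(x))
  pending <- which(is.na(value) & !is.na(x))
  for (i in pending) {
    parts <- suppressWarnings(as.numeric(strsplit(trimws(x[i]), "\\s*[-/]\\s*")[[1]]))
    if (length(parts) >= 2 && all(is.finite(parts))) {
      value[i] <- mean(parts)
      original[i] <- paste0("temperature_as_given=", x[i])
    }
  }
  list(value = value, original = original)
}

paste_conditions <- function(cond, extra) {
  ifelse(is.na(cond) | cond == "", extra, paste(cond, extra, sep = "; "))
}

new_record_table <- function(tbl, filter_log = NULL, source = NA_character_) {
  attr(tbl, "filter_log") <- filter_log
  attr(tbl, "source") <- source
  class(tbl) <- unique(c("record_table", class(tbl)))
  tbl
}

#' Read a growth-record file and harmonize it
#'
#' Reads a CSV (or, with readxl installed, an XLSX spreadsheet) of literature
#' growth records, renames columns through an optional column map, and passes
#' the rows through [harmonize_records()]. The column map lets the same
#' reader digest files with arbitrary headers: it is a named character vector
#' `c(canonical = "header in file", ...)`, or a YAML file of the same
#' structure.
#'
#' @param path Path to the records file.
#' @param format `"auto"` (by extension), `"csv"`, or `"xlsx"`.
#' @param column_map Optional named character vector or YAML file path
#'   mapping canonical column names to the file's headers.
#' @param ... Passed to [harmonize_records()].
#' @return A `record_table` (see [harmonize_records()]).
#' @export
load_records <- function(path, format = c("auto", "csv", "xlsx"),
                         column_map = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheets requires the readxl package", call. = FALSE)
    }
    readxl::read_excel(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(column_map) && length(column_map) == 1 && file.exists(column_map)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML column maps require the yaml package", call. = FALSE)
    }
    column_map <- unlist(yaml::read_yaml(column_map))
  }
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      stop("column map refers to absent columns: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    names(raw)[match(unname(column_map), names(raw))] <- names(column_map)
  }
  # aliases used by the canonical harmonized CSV round-trip
  aliases <- c(temperature = "temperature_C", rgr = "rgr_per_day")
  for (canon in names(aliases)) {
    if (!canon %in% names(raw) && aliases[[canon]] %in% names(raw)) {
      names(raw)[names(raw) == aliases[[canon]]] <- canon
    }
  }
  mandatory <- c("species", "temperature")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("missing mandatory columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- harmonize_records(raw, ...)
  attr(out, "source") <- path
  out
}

#' Subset a record table to one or more species
#'
#' Order-preserving subset; the before/after counts are appended to the
#' table's filter log so provenance survives the pipeline.
#'
#' @param table A `record_table`.
#' @param species Character vector of controlled species labels.
#' @return The filtered `record_table`.
#' @export
filter_species <- function(table, species) {
  bad <- setdiff(species, azolla_species())
  if (length(bad)) {
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  before <- nrow(table)
  out <- table[table$species %in% species, , drop = FALSE]
  log <- attr(table, "filter_log")
  entry <- tibble::tibble(
    row = NA_integer_,
    reason = sprintf("filter_species(%s): %d -> %d records",
                     paste(species, collapse = "+"), before, nrow(out))
  )
  new_record_table(out,
                   filter_log = dplyr::bind_rows(log, entry),
                   source = attr(table, "source"))
}

#' Write a record table as the canonical harmonized CSV
#'
#' Fixed column order: `study_id, species, strain, temperature_C,
#' rgr_per_day, rgr_source, sd, conditions`.
#'
#' @param table A `record_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(table, path) {
  out <- tibble::tibble(
    study_id = table$study_id, species = table$species,
    strain = table$strain, temperature_C = table$temperature,
    rgr_per_day = table$rgr, rgr_source = table$rgr_source,
    sd = table$sd, conditions = table$conditions
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
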