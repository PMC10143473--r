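#' Industry-type codes recognised in region tables
#'
#' Six industrial region types: `M` mining areas; `S` heavy-metal processing
#' and smelting areas; `E-w` e-waste treatment and disposal sites; `El`
#' electroplating sites; `T` tanning and tannery-sludge storage sites; `C`
#' chromium-salt production and chromite-ore processing residue (COPR)
#' disposal areas.
#'
#' @format Character vector of length 6.
#' @export
industry_types <- c("M", "S", "E-w", "El", "T", "C")

.region_columns <- c("region_id", "province", "city", "industry_type",
                     "sampling_year", "depth_cm", "cr_conc", "source")
.required_columns <- c("region_id", "province", "industry_type", "cr_conc")

#' Validate a region table
#'
#' Checks the invariants every downstream stage relies on: positive total-Cr
#' concentration, a known industry-type code, and (when present) a plausible
#' sampling year and non-negative depth. Problems are reported with row
#' numbers so offending records can be located in the source CSV.
#'
#' @param regions Data frame with at least columns `region_id`, `province`,
#'   `industry_type`, `cr_conc` (mg/kg); optional `city`, `sampling_year`,
#'   `depth_cm`, `source`.
#' @return The validated data frame (invisibly normalised: all eight standard
#'   columns present, missing optionals filled with `NA`).
#' @export
validate_regions <- function(regions) {
  if (!is.data.frame(regions)) {
    stop_input("region table must be a data frame")
  }
  missing_cols <- setdiff(.required_columns, names(regions))
  if (length(missing_cols) > 0) {
    stop_input("region table is missing required column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.region_columns, names(regions))) {
    regions[[col]] <- NA
  }
  regions <- regions[.region_columns]
  regions$region_id <- as.character(regions$region_id)
  regions$province <- as.character(regions$province)
  regions$city <- as.character(regions$city)
  regions$industry_type <- as.character(regions$industry_type)
  regions$source <- as.character(regions$source)

  problems <- character(0)
  note <- function(rows, fmt, vals) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf(fmt, rows, vals))
    }
  }

  cr <- suppressWarnings(as.numeric(regions$cr_conc))
  bad <- which(is.na(cr) | cr <= 0)
  note(bad, "row %d: cr_conc must be a positive number, got '%s'",
       as.character(regions$cr_conc)[bad])
  regions$cr_conc <- cr

  bad <- which(!regions$industry_type %in% industry_types)
  note(bad,
       paste0("row %d: unknown industry_type '%s' (allowed: ",
              paste(industry_types, collapse = ", "), ")"),
       regions$industry_type[bad])

  yr <- suppressWarnings(as.integer(regions$sampling_year))
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  bad <- which(!is.na(regions$sampling_year) &
                 (is.na(yr) | yr < 1990L | yr > this_year))
  note(bad, "row %d: sampling_year '%s' outside 1990..current year",
       as.character(regions$sampling_year)[bad])
  regions$sampling_year <- yr

  dp <- suppressWarnings(as.numeric(regions$depth_cm))
  bad <- which(!is.na(regions$depth_cm) & (is.na(dp) | dp < 0))
  note(bad, "row %d: depth_cm '%s' must be non-negative",
       as.character(regions$depth_cm)[bad])
  regions$depth_cm <- dp

  if (length(problems) > 0) {
    stop_input("invalid region table:\n%s", paste(problems, collapse = "\n"))
  }
  rownames(regions) <- NULL
  regions
}

#' Read a region table from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row containing at least
#' `region_id,province,industry_type,cr_conc`; the full column set is
#' `region_id,province,city,industry_type,sampling_year,depth_cm,cr_conc,source`.
#' Rows violating the record invariants abort the read with row-numbered
#' diagnostics.
#'
#' @param path Path to the CSV file (or a connection).
#' @return Validated region data frame.
#' @seealso [write_region_table()], [validate_regions()]
#' @export
read_region_table <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    stop_input("region table file not found: %s", path)
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("NA", "")),
    error = function(e) stop_input("cannot read region CSV: %s", conditionMessage(e))
  )
  validate_regions(raw)
}

#' Write a region table to CSV
#'
#' @param regions Region data frame (validated on the way out).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  regions <- validate_regions(regions)
  utils::write.csv(regions, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Background (reference) soil Cr concentrations
#'
#' Builds the lookup table of geochemical background values Bn. Lookups fall
#' back to the national default (61 mg/kg, the national soil Cr background)
#' for provinces without a specific entry; provincial values are supplied by
#' the user, typically through the assessment config.
#'
#' @param per_province Named numeric vector, province -> Bn (mg/kg). May be
#'   empty.
#' @param national_default Positive number (mg/kg). Default 61.
#' @return Object of class `cr_background`.
#' @export
background_table <- function(per_province = numeric(0), national_default = 61) {
  per_province <- unlist(per_province)
  if (is.null(per_province)) per_province <- numeric(0)
  if (length(per_province) > 0) {
    if (is.null(names(per_province)) || any(names(per_province) == "")) {
      stop_config("per_province background values must be named by province")
    }
    if (any(!is.finite(per_province) | per_province <= 0)) {
      stop_config("all provincial background values must be positive")
    }
  }
  if (!is.numeric(national_default) || length(national_default) != 1 ||
      !is.finite(national_default) || national_default <= 0) {
    stop_config("national_default background must be a positive number")
  }
  structure(list(per_province = per_province,
                 national_default = national_default),
            class = "cr_background")
}

#' Look up the background value for one or more provinces
#'
#' @param table A [background_table()].
#' @param province Character vector of province names.
#' @return Numeric vector of Bn values (mg/kg); unknown provinces get the
#'   national default.
#' @export
lookup_background <- function(table, province) {
  stopifnot(inherits(table, "cr_background"))
  bn <- unname(table$per_province[as.character(province)])
  bn[is.na(bn)] <- table$national_default
  bn
}

#' @export
print.cr_background <- function(x, ...) {
  cat(sprintf("Soil Cr background table: %d provincial value(s), national default %.4g mg/kg\n",
              length(x$per_province), x$national_default))
  invisible(x)
}

#' Descriptive statistics of a region table
#'
#' Sample statistics of the total-Cr concentrations plus two exceedance
#' rates: the share of regions above their own province's background value
#' and the share above the regulatory screening value (2500 mg/kg for total
#' Cr in industrial land by default). Comparisons are strict (`>`) unless
#' `strict = FALSE`; the standard deviation uses the unbiased (n-1)
#' denominator and the coefficient of variation is `100 * sd / mean`.
#'
#' @param regions Region data frame.
#' @param background A [background_table()]; default is the national-only
#'   table (61 mg/kg everywhere).
#' @param screening Screening value in mg/kg (default 2500).
#' @param strict Logical; `TRUE` compares with `>`, `FALSE` with `>=`.
#' @return Object of class `cr_summary`: list with `n`, `min`, `max`, `mean`,
#'   `median`, `sd`, `cv_pct`, `pct_above_background`, `pct_above_screening`.
#' @export
describe_regions <- function(regions, background = background_table(),
                             screening = 2500, strict = TRUE) {
  regions <- validate_regions(regions)
  if (nrow(regions) == 0) stop_input("cannot describe an empty region table")
  x <- regions$cr_conc
  bn <- lookup_background(background, regions$province)
  cmp <- if (strict) `>` else `>=`
  s <- stats::sd(x)
  m <- mean(x)
  structure(list(
    n = length(x),
    min = min(x), max = max(x),
    mean = m, median = stats::median(x), sd = s,
    cv_pct = 100 * s / m,
    pct_above_background = 100 * mean(cmp(x, bn)),
    pct_above_screening = 100 * mean(cmp(x, screening)),
    screening = screening
  ), class = "cr_summary")
}

#' @export
print.cr_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Soil Cr concentrations, n = %d regions\n", x$n))
  cat(sprintf("  range   %.2f - %.2f mg/kg\n", x$min, x$max))
  cat(sprintf("  mean    %.2f mg/kg   median %.2f mg/kg   sd %.2f\n",
              x$mean, x$median, x$sd))
  cat(sprintf("  CV      %.2f%%\n", x$cv_pct))
  cat(sprintf("  above background value:      %.2f%%\n", x$pct_above_background))
  cat(sprintf("  above screening (%g mg/kg):  %.2f%%\n",
              x$screening, x$pct_above_screening))
  invisible(x)
}
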