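# Registry data model: one row per enrolled pregnancy, gestational ages in
# integer days since LMP, outcome one of four terminal states.

OUTCOME_LEVELS   <- c("MISCARRIAGE", "MTP", "STILLBIRTH", "LIVEBIRTH")
LOSS_OUTCOMES    <- c("MISCARRIAGE", "MTP")
EDUCATION_LEVELS <- c("NONE", "PRIMARY", "SECONDARY", "UNIVERSITY_PLUS")
ATTENDANT_LEVELS <- c("PHYSICIAN", "NURSE_MIDWIFE", "TBA", "FAMILY_SELF_OTHER")
LOCATION_LEVELS  <- c("HOSPITAL", "CLINIC_HEALTH_CENTER", "HOME_OTHER")

# canonical column -> (type, required)
REGISTRY_COLUMNS <- list(
  woman_id             = list(type = "character", required = TRUE),
  cluster_id           = list(type = "character", required = TRUE),
  enroll_ga_days       = list(type = "integer",   required = TRUE),
  outcome              = list(type = "outcome",   required = TRUE),
  outcome_ga_days      = list(type = "integer",   required = TRUE),
  neonatal_death_by_28d = list(type = "logical",  required = FALSE),
  maternal_age_years   = list(type = "integer",   required = FALSE),
  education            = list(type = "education", required = FALSE),
  parity               = list(type = "integer",   required = FALSE),
  weight_kg            = list(type = "numeric",   required = FALSE),
  height_m             = list(type = "numeric",   required = FALSE),
  hemoglobin_g_dl      = list(type = "numeric",   required = FALSE),
  anc_visits           = list(type = "integer",   required = FALSE),
  attendant            = list(type = "attendant", required = FALSE),
  location             = list(type = "location",  required = FALSE)
)

registry_levels <- function(type) {
  switch(type,
         outcome = OUTCOME_LEVELS, education = EDUCATION_LEVELS,
         attendant = ATTENDANT_LEVELS, location = LOCATION_LEVELS,
         NULL)
}

#' Read a pregnancy registry from a delimited file
#'
#' Reads a comma-delimited, UTF-8 registry export with a mandatory header
#' row into a registry data frame (one row per pregnancy, canonical column
#' names, gestational ages in days since LMP). Rows whose cells cannot be
#' coerced to the expected type are rejected row-by-row, never silently
#' dropped: the returned data frame carries a `rejections` attribute naming
#' each bad row, field and reason, and counts are reported via `message()`.
#'
#' @param path Path to a CSV file.
#' @param schema Optional column remapping: a named character vector
#'   (canonical name -> file column name) or the path to a YAML/JSON file
#'   holding such a mapping. Unmapped canonical names are looked up
#'   directly.
#' @param quiet Suppress the read/rejected count message.
#' @return A `data.frame` with the canonical registry columns, plus
#'   attribute `rejections` (a data frame with columns `row`, `field`,
#'   `reason`; zero rows when everything parsed).
#' @seealso [write_registry()], [validate_registry()]
#' @export
read_registry <- function(path, schema = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  map <- resolve_schema(schema)
  missing_cols <- character(0)
  for (col in names(REGISTRY_COLUMNS)) {
    src <- if (col %in% names(map)) map[[col]] else col
    if (!src %in% names(raw)) {
      if (REGISTRY_COLUMNS[[col]]$required) missing_cols <- c(missing_cols, src)
      raw[[src]] <- NA_character_
    }
    names(raw)[names(raw) == src] <- col
  }
  if (length(missing_cols))
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[names(REGISTRY_COLUMNS)]

  rejections <- data.frame(row = integer(0), field = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  out <- raw
  for (col in names(REGISTRY_COLUMNS)) {
    spec <- REGISTRY_COLUMNS[[col]]
    x <- raw[[col]]
    coerced <- switch(spec$type,
      character = x,
      integer   = suppressWarnings(as.integer(x)),
      numeric   = suppressWarnings(as.numeric(x)),
      logical   = parse_logical(x),
      { lv <- registry_levels(spec$type); ifelse(x %in% lv, x, NA_character_) })
    bad <- which(!is.na(x) & is.na(coerced))
    if (length(bad))
      rejections <- rbind(rejections, data.frame(
        row = bad, field = col,
        reason = sprintf("cannot parse %s value '%s'", spec$type, x[bad]),
        stringsAsFactors = FALSE))
    out[[col]] <- coerced
  }
  bad_rows <- sort(unique(rejections$row))
  if (length(bad_rows)) out <- out[-bad_rows, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    message(sprintf("read_registry: %d record(s) read, %d row(s) rejected from %s",
                    nrow(out), length(bad_rows), path))
  attr(out, "rejections") <- rejections
  out
}

parse_logical <- function(x) {
  up <- toupper(x)
  ifelse(up %in% c("TRUE", "T", "1", "YES"), TRUE,
         ifelse(up %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
}

resolve_schema <- function(schema) {
  if (is.null(schema)) return(character(0))
  if (is.character(schema) && length(schema) == 1 && is.null(names(schema))) {
    if (!file.exists(schema)) stop("schema file not found: ", schema)
    schema <- unlist(yaml::read_yaml(schema))
  }
  if (is.list(schema)) schema <- unlist(schema)
  if (is.null(names(schema)) || any(names(schema) == ""))
    stop("schema must map canonical column names to file column names")
  unknown <- setdiff(names(schema), names(REGISTRY_COLUMNS))
  if (length(unknown))
    stop("schema names unknown canonical column(s): ", paste(unknown, collapse = ", "))
  schema
}

#' Write a registry to CSV
#'
#' Writes the canonical comma-delimited dialect that [read_registry()] reads
#' back field-for-field (UTF-8, header row, empty cells for missing values).
#'
#' @param records Registry data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  records <- records[intersect(names(REGISTRY_COLUMNS), names(records))]
  utils::write.csv(records, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate registry records against the data model
#'
#' Checks every row against the registry invariants and returns the
#' violations as data, one row per broken rule — validation never throws.
#' Rules checked: outcome before enrollment; miscarriage at/after 20 weeks
#' (140 days); stillbirth before 20 weeks; the neonatal-survival flag
#' present exactly for live births; negative gestational ages, parity or
#' antenatal visit counts; non-positive weight or height.
#'
#' @param records Registry data frame.
#' @return Data frame with columns `row`, `woman_id`, `field`, `rule`;
#'   zero rows when all records conform.
#' @export
validate_registry <- function(records) {
  v <- list()
  flag <- function(idx, field, rule) {
    if (any(idx, na.rm = TRUE)) {
      i <- which(idx)
      v[[length(v) + 1]] <<- data.frame(
        row = i, woman_id = as.character(records$woman_id[i]),
        field = field, rule = rule, stringsAsFactors = FALSE)
    }
  }
  out  <- records$outcome
  oga  <- records$outcome_ga_days
  ega  <- records$enroll_ga_days
  flag(!is.na(ega) & ega < 0, "enroll_ga_days", "enrollment gestational age must be >= 0")
  flag(!is.na(ega) & !is.na(oga) & oga < ega, "outcome_ga_days",
       "outcome gestational age before enrollment")
  flag(!is.na(out) & out == "MISCARRIAGE" & !is.na(oga) & oga >= GA_20_WEEKS,
       "outcome_ga_days", "miscarriage at/after 140 days (20 weeks)")
  flag(!is.na(out) & out == "STILLBIRTH" & !is.na(oga) & oga < GA_20_WEEKS,
       "outcome_ga_days", "stillbirth before 140 days (20 weeks)")
  flag(!is.na(out) & out == "LIVEBIRTH" & is.na(records$neonatal_death_by_28d),
       "neonatal_death_by_28d", "missing neonatal-survival flag for live birth")
  flag(!is.na(out) & out != "LIVEBIRTH" & !is.na(records$neonatal_death_by_28d),
       "neonatal_death_by_28d", "neonatal-survival flag on a non-livebirth outcome")
  flag(!is.na(records$parity) & records$parity < 0, "parity", "negative parity")
  flag(!is.na(records$anc_visits) & records$anc_visits < 0, "anc_visits",
       "negative antenatal visit count")
  flag(!is.na(records$weight_kg) & records$weight_kg <= 0, "weight_kg",
       "non-positive weight")
  flag(!is.na(records$height_m) & records$height_m <= 0, "height_m",
       "non-positive height")
  if (!length(v))
    return(data.frame(row = integer(0), woman_id = character(0),
                      field = character(0), rule = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, v)
  res <- res[order(res$row), ]
  rownames(res) <- NULL
  res
}

#' @rdname validate_registry
#' @param record A single-row registry data frame.
#' @export
validate_record <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  validate_registry(record)
}

#' Exclude records without usable gestational-age information
#'
#' Drops records missing the enrollment gestational age and records enrolled
#' at (or after) the pregnancy's end — neither contributes person-time to any
#' interval. The operation is idempotent.
#'
#' @param records Registry data frame.
#' @return List with `records` (the retained rows) and `n_excluded`.
#' @export
exclude_unknown_ga <- function(records) {
  keep <- !is.na(records$enroll_ga_days) &
    (is.na(records$outcome_ga_days) |
       records$enroll_ga_days < records$outcome_ga_days)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, n_excluded = nrow(records) - nrow(kept))
}
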