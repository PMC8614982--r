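#' @keywords internal
"_PACKAGE"

#' Canonical CASA kinematic variable names
#'
#' The eight per-spermatozoon kinematic descriptors produced by CASA systems:
#' curvilinear velocity (VCL, um/s), straight-line velocity (VSL, um/s),
#' average-path velocity (VAP, um/s), linearity (LIN = 100*VSL/VCL, %),
#' straightness (STR = 100*VSL/VAP, %), wobble (WOB = 100*VAP/VCL, %),
#' amplitude of lateral head displacement (ALH, um) and beat-cross frequency
#' (BCF, Hz).
#'
#' @export
KINEMATIC_VARS <- c("VCL", "VSL", "VAP", "LIN", "STR", "WOB", "ALH", "BCF")

## Canonical column order of a kinematic table.
CASA_COLUMNS <- c(KINEMATIC_VARS,
                  "sample_type", "medium", "time_min", "replicate_id", "sperm_id")

SAMPLE_TYPES <- c("fresh", "frozen_thawed")
MEDIA <- c("CAP", "NC")

## Incubation-time design grid (minutes) per medium.
CAP_TIMES <- c(1, 5, 15, 30, 60, 120, 180, 240)
NC_TIMES <- c(0, 15, 240)

#' Construct a kinematic dataset
#'
#' A `kinematic_dataset` bundles a validated per-spermatozoon kinematic table
#' with its load report and provenance. Rows violating hard invariants
#' (negative velocities, ratio descriptors outside \[0, 100\], velocity
#' ordering VSL <= VAP <= VCL, or the ratio identities LIN = 100*VSL/VCL,
#' STR = 100*VSL/VAP, WOB = 100*VAP/VCL beyond `ratio_tol`) are dropped and
#' counted, never repaired.
#'
#' @param records data.frame with columns `VCL, VSL, VAP, LIN, STR, WOB, ALH,
#'   BCF, sample_type, medium, time_min, replicate_id, sperm_id`.
#' @param provenance character scalar identifying the source (path or
#'   scenario id).
#' @param ratio_tol relative tolerance for the ratio identities (default 2%,
#'   absorbing CASA export rounding).
#' @param allow_off_grid if `FALSE` (default), incubation times must come from
#'   the design grid (CAP: 1, 5, 15, 30, 60, 120, 180, 240 min; NC: 0, 15,
#'   240 min).
#' @return An object of class `kinematic_dataset`: a list with elements
#'   `records` (the validated data.frame), `report` (drop counts by reason)
#'   and `provenance`.
#' @export
kinematic_dataset <- function(records, provenance = NA_character_,
                              ratio_tol = 0.02, allow_off_grid = FALSE) {
  missing_cols <- setdiff(CASA_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, CASA_COLUMNS]
  val <- validate_kinematic_records(records, ratio_tol = ratio_tol)
  records <- val$records
  if (nrow(records) == 0L) {
    stop("no valid kinematic records after validation")
  }

  bad_type <- !records$sample_type %in% SAMPLE_TYPES
  bad_med <- !records$medium %in% MEDIA
  if (any(bad_type)) stop("unknown sample_type: ",
                          paste(unique(records$sample_type[bad_type]), collapse = ", "))
  if (any(bad_med)) stop("unknown medium: ",
                         paste(unique(records$medium[bad_med]), collapse = ", "))
  if (!allow_off_grid) {
    off <- (records$medium == "CAP" & !records$time_min %in% CAP_TIMES) |
      (records$medium == "NC" & !records$time_min %in% NC_TIMES)
    if (any(off)) {
      stop("time_min values off the design grid (set allow_off_grid = TRUE to keep them): ",
           paste(unique(records$time_min[off]), collapse = ", "))
    }
  }

  structure(list(records = records, report = val$report, provenance = provenance),
            class = "kinematic_dataset")
}

## Row-level invariant checks. Returns kept rows plus a named drop count.
validate_kinematic_records <- function(df, ratio_tol = 0.02) {
  num_cols <- KINEMATIC_VARS
  m <- as.data.frame(lapply(df[num_cols], as.numeric))

  rel_ok <- function(observed, expected) {
    ## relative agreement with identity value; exact zero/zero pairs pass
    ifelse(expected == 0, observed == 0,
           abs(observed - expected) <= ratio_tol * abs(expected))
  }

  checks <- list(
    non_finite = !stats::complete.cases(m) | !apply(is.finite(as.matrix(m)), 1, all),
    negative_velocity = m$VCL < 0 | m$VSL < 0 | m$VAP < 0 | m$ALH < 0 | m$BCF < 0,
    ratio_out_of_range = m$LIN < 0 | m$LIN > 100 | m$STR < 0 | m$STR > 100 |
      m$WOB < 0 | m$WOB > 100,
    velocity_order = m$VSL > m$VAP * (1 + ratio_tol) | m$VAP > m$VCL * (1 + ratio_tol),
    lin_identity = ifelse(m$VCL > 0, !rel_ok(m$LIN, 100 * m$VSL / m$VCL), FALSE),
    str_identity = ifelse(m$VAP > 0, !rel_ok(m$STR, 100 * m$VSL / m$VAP), FALSE),
    wob_identity = ifelse(m$VCL > 0, !rel_ok(m$WOB, 100 * m$VAP / m$VCL), FALSE)
  )
  checks <- lapply(checks, function(x) {
    x[is.na(x)] <- TRUE
    x
  })
  bad <- Reduce(`|`, checks)
  report <- c(n_input = nrow(df), n_dropped = sum(bad),
              vapply(checks, sum, integer(1)))
  df[num_cols] <- m
  list(records = df[!bad, , drop = FALSE], report = report)
}

#' Read a CASA kinematic table from CSV
#'
#' Ingests a per-spermatozoon CASA export. Non-canonical column names are
#' handled through `column_map`; rows failing hard kinematic invariants are
#' dropped and counted in the load report.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping canonical names
#'   to file column names, e.g. `c(VCL = "Curvilinear")`.
#' @param delim field delimiter (default ",").
#' @param dec decimal mark, "." or ",".
#' @inheritParams kinematic_dataset
#' @return A [kinematic_dataset].
#' @export
read_casa_table <- function(path, column_map = NULL, delim = ",", dec = ".",
                            ratio_tol = 0.02, allow_off_grid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim, dec = dec,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column not found in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  kinematic_dataset(df, provenance = path, ratio_tol = ratio_tol,
                    allow_off_grid = allow_off_grid)
}

#' Write a kinematic dataset to CSV in canonical column order
#'
#' @param ds a [kinematic_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_casa_table <- function(ds, path) {
  stopifnot(inherits(ds, "kinematic_dataset"))
  utils::write.csv(ds$records[, CASA_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Retain motile spermatozoa
#'
#' Kinematic descriptors are only meaningful for motile cells. CASA systems
#' apply an internal motility cutoff that vendors rarely document; here the
#' convention is a configurable VCL (and optionally VAP) floor.
#'
#' @param ds a [kinematic_dataset].
#' @param vcl_min minimum curvilinear velocity (um/s), default 10.
#' @param vap_min minimum average-path velocity (um/s), default 0.
#' @return A [kinematic_dataset] of the retained records; the number removed
#'   is recorded in `$report["n_filtered_immotile"]`.
#' @export
filter_motile <- function(ds, vcl_min = 10, vap_min = 0) {
  stopifnot(inherits(ds, "kinematic_dataset"), vcl_min >= 0, vap_min >= 0)
  keep <- ds$records$VCL >= vcl_min & ds$records$VAP >= vap_min
  if (!any(keep)) {
    stop("filter_motile removed every record (vcl_min = ", vcl_min,
         ", vap_min = ", vap_min, "); clustering cannot proceed")
  }
  out <- ds
  out$records <- ds$records[keep, , drop = FALSE]
  out$report <- c(ds$report, n_filtered_immotile = sum(!keep))
  out
}

#' @export
print.kinematic_dataset <- function(x, ...) {
  cat("<kinematic_dataset> ", nrow(x$records), " records, provenance: ",
      x$provenance, "\n", sep = "")
  tab <- table(x$records$sample_type, x$records$medium)
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.kinematic_dataset <- function(x, ...) x$records
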