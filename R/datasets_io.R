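.record_cols <- c("study", "endpoint", "d1_gy", "d2_gy", "dt_h", "t_h",
                  "n2_events", "n2_denom", "n12_events", "n12_denom", "delta")

.bundle_files <- c(
  shadley_lesions     = "table2_shadley_lesions.csv",
  shadley_aberrations = "table2_shadley_aberrations.csv",
  day_inversions      = "table3_day_inversions.csv"
)

new_dataset_bundle <- function(records, endpoint_class, provenance) {
  structure(list(records = records,
                 endpoint_class = endpoint_class,
                 provenance = provenance),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("Two-dose experiment bundle: %d records (%s endpoint)\n",
              nrow(x$records), x$endpoint_class))
  cat(" ", x$provenance, "\n")
  print(utils::head(x$records, 4))
  if (nrow(x$records) > 4) cat("  ...\n")
  invisible(x)
}

# round half away from zero, matching how the printed tables round delta
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Load a bundled calibration dataset
#'
#' The transcribed published two-dose experiments: chromatid/isochromatid
#' break counts and chromosome aberration counts in human lymphocytes
#' (three studies by Shadley and collaborators) and chromosomal inversion
#' frequencies in mouse prostate and spleen (two studies by Day and
#' collaborators; doses already converted from mGy to Gy). Each record
#' carries the priming dose `d1_gy`, challenging dose `d2_gy`, inter-dose
#' interval `dt_h`, observation time `t_h`, the event counts (or
#' frequencies, with `n2_denom = 1`) of both arms, the published delta, and
#' per-row provenance (`study`, `source_table`, `footnote`; footnote `d`
#' marks negative-delta rows, kept for calibration).
#'
#' @param name One of `"shadley_lesions"` (23 lesion records),
#'   `"shadley_aberrations"` (10 aberration records),
#'   `"day_inversions"` (8 inversion records), or `"all_table2"`
#'   (the 33 pooled lymphocyte records).
#' @return A `dataset_bundle`.
#' @export
load_bundled <- function(name) {
  choices <- c(names(.bundle_files), "all_table2")
  if (length(name) != 1L || !name %in% choices)
    stop("unknown bundled dataset; available: ",
         paste(choices, collapse = ", "), call. = FALSE)
  read_one <- function(key) {
    path <- system.file("extdata", .bundle_files[[key]],
                        package = "primingdose", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (name == "all_table2") {
    rec <- rbind(read_one("shadley_lesions"), read_one("shadley_aberrations"))
    return(new_dataset_bundle(rec, "lesions",
                              "pooled lymphocyte data (lesions + aberrations)"))
  }
  rec <- read_one(name)
  cls <- if (name == "day_inversions") "mutations" else "lesions"
  prov <- switch(name,
    shadley_lesions = "human lymphocyte chromatid breaks, two studies",
    shadley_aberrations = "human lymphocyte chromosome aberrations",
    day_inversions = "mouse chromosomal inversions (frequencies, doses in Gy)")
  new_dataset_bundle(rec, cls, prov)
}

#' Read two-dose experiment records from CSV
#'
#' Expects the same column schema as the bundled data (header required):
#' `study, endpoint, d1_gy, d2_gy, dt_h, t_h, n2_events, n2_denom,
#' n12_events, n12_denom, delta`. Extra columns are carried through.
#'
#' @param path CSV file path.
#' @param dose_unit Unit of the dose columns in the file; `"mGy"` values are
#'   divided by 1000 on load.
#' @param endpoint_class `"lesions"` or `"mutations"`, used by fitting to
#'   pick the delta formula.
#' @return A `dataset_bundle`.
#' @export
read_records_csv <- function(path, dose_unit = c("Gy", "mGy"),
                             endpoint_class = c("lesions", "mutations")) {
  dose_unit <- match.arg(dose_unit)
  endpoint_class <- match.arg(endpoint_class)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.record_cols, names(rec))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num_cols <- setdiff(.record_cols, c("study", "endpoint"))
  problems <- character()
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(rec[[cc]]))
    bad <- which(is.na(v) & !is.na(rec[[cc]]) & rec[[cc]] != "")
    if (length(bad))
      problems <- c(problems, sprintf("row %s: non-numeric '%s'",
                                      paste(bad, collapse = ","), cc))
    rec[[cc]] <- v
  }
  if (length(problems))
    stop("malformed records:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  if (dose_unit == "mGy") {
    rec$d1_gy <- rec$d1_gy / 1000
    rec$d2_gy <- rec$d2_gy / 1000
  }
  bad_t <- which(!is.na(rec$t_h) & rec$dt_h >= rec$t_h)
  if (length(bad_t))
    stop("rows with dt_h >= t_h: ", paste(bad_t, collapse = ", "),
         call. = FALSE)
  if (any(rec$d1_gy < 0 | rec$d2_gy < 0))
    stop("negative doses in file", call. = FALSE)
  new_dataset_bundle(rec, endpoint_class, paste("read from", path))
}

#' Write a bundle to CSV
#'
#' @param bundle A `dataset_bundle`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(bundle, path) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  utils::write.csv(bundle$records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Check published deltas against their own counts
#'
#' Recomputes delta from each record's counts via [delta_from_counts()] and
#' compares with the published `delta` column at the printed 3-decimal
#' precision (tolerance 5e-4 plus rounding).
#'
#' @param bundle A `dataset_bundle`.
#' @param tol Pass threshold on `|recomputed - printed|`.
#' @return A data frame report with one row per record (`delta_printed`,
#'   `delta_recomputed`, `abs_diff`, `pass`) and attribute `all_pass`.
#' @export
validate_printed_deltas <- function(bundle, tol = 5e-4) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  rec <- bundle$records
  recomputed <- delta_from_counts(rec$n2_events, rec$n2_denom,
                                  rec$n12_events, rec$n12_denom)
  diff <- abs(recomputed - rec$delta)
  pass <- diff <= tol | round_half_up(recomputed, 3) == rec$delta
  report <- data.frame(study = rec$study,
                       delta_printed = rec$delta,
                       delta_recomputed = recomputed,
                       abs_diff = diff,
                       pass = pass)
  attr(report, "all_pass") <- all(pass)
  report
}
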