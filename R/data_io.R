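#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis rnorm rbinom rlnorm median quantile sd
#'   pnorm qnorm optim nlminb optimHess runif setNames aggregate dnorm
#' @importFrom utils read.table write.table packageVersion
NULL

INSTRUMENTS <- c("CAM", "3DCAM")
FEATURES <- c("acute_change", "inattention", "disorganized_thinking", "aloc")
REQUIRED_COLUMNS <- c("patient_id", "occasion_id", "instrument", "rater_id",
                      "delirium", FEATURES)
BINARY_COLUMNS <- c("delirium", FEATURES)

#' Read a long-format assessment table
#'
#' Reads a delimited text file with one row per instrument administration:
#' one (patient, occasion, instrument) triple with the rater who scored it,
#' the binary overall delirium outcome, the four binary cardinal features
#' (acute change and fluctuating course, inattention, disorganized thinking,
#' altered level of consciousness), and an optional administration duration
#' in minutes.
#'
#' @param path Path to a comma- or tab-delimited file with a header row.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A validated `data.frame` of assessment records (see
#'   [validate_assessments()]).
#' @seealso [write_assessments()], [pair_assessments()], [summarize_cohort()]
#' @export
read_assessments <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
  validate_assessments(tab)
}

#' Validate an assessment table
#'
#' Checks the schema and value contracts of a long-format assessment table:
#' required columns present, instrument coded `"CAM"`/`"3DCAM"`, outcome
#' fields exactly 0/1, no duplicate (patient, occasion, instrument) triple,
#' and feature values missing only where the overall delirium outcome is
#' observed.  Missing feature values are allowed (those rows are dropped
#' from that feature's analysis downstream, with a message).
#'
#' @param tab A data.frame-like object with the assessment columns.
#' @return The validated table with typed columns, invisibly classed
#'   `"assessment_table"`.
#' @export
validate_assessments <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("patient_id", "occasion_id", "rater_id"))
    tab[[col]] <- as.character(tab[[col]])
  bad_inst <- !tab$instrument %in% INSTRUMENTS
  if (any(bad_inst))
    stop("validation error: instrument must be one of ",
         paste(INSTRUMENTS, collapse = "/"), "; offending row ",
         which(bad_inst)[1L])
  for (col in BINARY_COLUMNS) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    present <- !is.na(tab[[col]])
    bad <- present & (is.na(v) | !(v %in% c(0, 1)))
    if (any(bad))
      stop("validation error: non-binary value in '", col, "' on row ",
           which(bad)[1L])
    if (col == "delirium" && any(!present))
      stop("validation error: missing delirium outcome on row ",
           which(!present)[1L])
    tab[[col]] <- as.integer(v)
  }
  if ("duration_minutes" %in% names(tab)) {
    d <- suppressWarnings(as.numeric(tab$duration_minutes))
    bad <- !is.na(tab$duration_minutes) & (is.na(d) | d < 0)
    if (any(bad))
      stop("validation error: duration_minutes must be a nonnegative number; ",
           "offending row ", which(bad)[1L])
    tab$duration_minutes <- d
  }
  key <- paste(tab$patient_id, tab$occasion_id, tab$instrument, sep = "\r")
  if (anyDuplicated(key))
    stop("duplication error: duplicate (patient, occasion, instrument) on row ",
         which(duplicated(key))[1L])
  class(tab) <- c("assessment_table", "data.frame")
  tab
}

#' Write an assessment table
#'
#' @param tab A validated assessment table.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_assessments <- function(tab, path, sep = ",") {
  write.table(as.data.frame(tab), path, sep = sep, row.names = FALSE,
              quote = FALSE, na = "NA")
  invisible(path)
}

#' Pair concurrent CAM and 3D-CAM administrations
#'
#' Builds one paired record per (patient, occasion) that has both
#' instruments; occasions carrying only one instrument are reported as
#' orphans (attribute `"orphans"` and a message), never silently dropped.
#' The two instruments of a pair were administered by two assessors who
#' approached the patient together, so a shared rater across the pair is
#' flagged.
#'
#' @param tab A validated assessment table.
#' @param same_rater What to do when the same rater scored both instruments
#'   of a pair: `"warn"` (default) or `"error"`.
#' @return A `data.frame` classed `"paired_assessments"` with one row per
#'   complete pair and per-instrument columns suffixed `_cam` / `_3dcam`,
#'   plus an `"orphans"` attribute listing incomplete occasions.
#' @export
pair_assessments <- function(tab, same_rater = c("warn", "error")) {
  same_rater <- match.arg(same_rater)
  tab <- as.data.frame(tab)
  key <- paste(tab$patient_id, tab$occasion_id, sep = "\r")
  cam <- tab[tab$instrument == "CAM", ]
  d3 <- tab[tab$instrument == "3DCAM", ]
  kc <- paste(cam$patient_id, cam$occasion_id, sep = "\r")
  k3 <- paste(d3$patient_id, d3$occasion_id, sep = "\r")
  common <- intersect(kc, k3)
  cam <- cam[match(common, kc), ]
  d3 <- d3[match(common, k3), ]
  value_cols <- c("rater_id", BINARY_COLUMNS,
                  intersect("duration_minutes", names(tab)))
  pairs <- data.frame(patient_id = cam$patient_id,
                      occasion_id = cam$occasion_id,
                      stringsAsFactors = FALSE)
  for (col in value_cols) {
    pairs[[paste0(col, "_cam")]] <- cam[[col]]
    pairs[[paste0(col, "_3dcam")]] <- d3[[col]]
  }
  orphan_keys <- setdiff(unique(key), common)
  orphans <- unique(tab[key %in% orphan_keys,
                        c("patient_id", "occasion_id", "instrument")])
  if (nrow(orphans))
    message(nrow(orphans), " occasion(s) with a single instrument reported ",
            "as orphans (not paired)")
  shared <- pairs$rater_id_cam == pairs$rater_id_3dcam
  if (any(shared)) {
    msg <- paste0(sum(shared), " pair(s) scored by the same rater on both ",
                  "instruments")
    if (same_rater == "error") stop(msg) else warning(msg)
  }
  attr(pairs, "orphans") <- orphans
  class(pairs) <- c("paired_assessments", "data.frame")
  pairs
}

#' Summarize an assessment cohort
#'
#' Counts distinct patients, complete concurrent CAM/3D-CAM pairs, and
#' raters, plus per-instrument positive counts and median administration
#' durations.
#'
#' @param tab A validated assessment table.
#' @return A list classed `"cohort_summary"` with elements `n_patients`,
#'   `n_pairs`, `n_raters`, `delirium_positive` (per instrument),
#'   `median_duration` (per instrument, minutes; `NA` if no durations).
#' @export
summarize_cohort <- function(tab) {
  tab <- as.data.frame(tab)
  if (nrow(tab) == 0L) stop("empty assessment table")
  key <- paste(tab$patient_id, tab$occasion_id, sep = "\r")
  n_pairs <- sum(vapply(split(tab$instrument, key),
                        function(ins) all(INSTRUMENTS %in% ins), logical(1)))
  pos <- vapply(INSTRUMENTS, function(ins)
    sum(tab$delirium[tab$instrument == ins]), numeric(1))
  med <- setNames(rep(NA_real_, 2L), INSTRUMENTS)
  if ("duration_minutes" %in% names(tab)) {
    for (ins in INSTRUMENTS) {
      d <- tab$duration_minutes[tab$instrument == ins]
      if (any(!is.na(d))) med[[ins]] <- median(d, na.rm = TRUE)
    }
  }
  out <- list(n_patients = length(unique(tab$patient_id)),
              n_pairs = n_pairs,
              n_raters = length(unique(tab$rater_id)),
              delirium_positive = as.list(pos),
              median_duration = as.list(med))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat("  patients:", x$n_patients, " concurrent pairs:", x$n_pairs,
      " raters:", x$n_raters, "\n")
  cat("  delirium positive: CAM", x$delirium_positive$CAM,
      " 3D-CAM", x$delirium_positive[["3DCAM"]], "\n")
  if (!all(is.na(unlist(x$median_duration))))
    cat("  median duration (min): CAM", x$median_duration$CAM,
        " 3D-CAM", x$median_duration[["3DCAM"]], "\n")
  invisible(x)
}
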