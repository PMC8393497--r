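#' Parse a patient-characteristics cohort table
#'
#' Reads the structured transcription of the study's patient table. Sample
#' count cells use the notation `"n (m)"`, meaning m of the n stereotactic
#' samples came from contrast-enhancing lesions; a bare `"n"` means no
#' enhancing samples; `"-"` means the modality was not performed (parsed as
#' absence, never as a zero-valued measurement, though the derived counts are
#' 0).
#'
#' @param path CSV with header columns `id, sex, age, pathology, molecular,
#'   met_pet, adc, samples_t1t2, samples_met, samples_adc`. The `met_pet` and
#'   `adc` columns hold `"Performed"` or `"-"`.
#' @return A data.frame of class `cohort_table` with columns `id`, `sex`,
#'   `age`, `pathology`, `molecular`, `met_pet_performed`, `adc_performed`,
#'   `n_samples_t1t2`, `n_samples_t1t2_enhancing`, `n_samples_met`,
#'   `n_samples_adc`.
#' @export
parse_cohort_table <- function(path) {
  if (!file.exists(path)) stop_relaxo("missing-file", "no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                  colClasses = "character")
  need <- c("id", "sex", "age", "pathology", "molecular", "met_pet", "adc",
            "samples_t1t2", "samples_met", "samples_adc")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_relaxo("parse", "cohort table missing columns: ",
                paste(missing_cols, collapse = ", "))
  t1t2 <- mapply(parse_count_cell, raw$samples_t1t2, seq_len(nrow(raw)),
                 MoreArgs = list(column = "samples_t1t2"), SIMPLIFY = FALSE)
  met <- mapply(parse_count_cell, raw$samples_met, seq_len(nrow(raw)),
                MoreArgs = list(column = "samples_met"), SIMPLIFY = FALSE)
  adc <- mapply(parse_count_cell, raw$samples_adc, seq_len(nrow(raw)),
                MoreArgs = list(column = "samples_adc"), SIMPLIFY = FALSE)
  out <- data.frame(
    id = raw$id,
    sex = raw$sex,
    age = as.integer(raw$age),
    pathology = raw$pathology,
    molecular = raw$molecular,
    met_pet_performed = raw$met_pet == "Performed",
    adc_performed = raw$adc == "Performed",
    n_samples_t1t2 = vapply(t1t2, `[[`, integer(1), "n"),
    n_samples_t1t2_enhancing = vapply(t1t2, `[[`, integer(1), "m"),
    n_samples_met = vapply(met, `[[`, integer(1), "n"),
    n_samples_adc = vapply(adc, `[[`, integer(1), "n"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$id))
    stop_relaxo("parse", "duplicate patient ids in cohort table")
  class(out) <- c("cohort_table", "data.frame")
  out
}

# One sample-count cell: "n", "n (m)" or "-". Returns list(n=, m=).
parse_count_cell <- function(cell, row, column) {
  cell <- trimws(cell)
  if (cell == "-" || cell == "")
    return(list(n = 0L, m = 0L))
  m <- regmatches(cell, regexec("^([0-9]+)(?:\\s*\\(([0-9]+)\\))?$", cell))[[1]]
  if (length(m) == 0L || m[1] != cell)
    stop_relaxo("parse", "malformed count cell '", cell, "' at row ", row,
                ", column ", column)
  n <- as.integer(m[2])
  enh <- if (is.na(m[3]) || m[3] == "") 0L else as.integer(m[3])
  if (enh > n)
    stop_relaxo("parse", "enhancing count ", enh, " exceeds sample count ", n,
                " at row ", row, ", column ", column)
  list(n = n, m = enh)
}

#' Parse a stereotactic biopsy table
#'
#' @param path CSV with header columns `patient_id, x, y, z, counts,
#'   enhancing`; `counts` holds the per-field cell counts joined by `";"`,
#'   `enhancing` is 0/1. Coordinates are world mm in the maps' frame.
#' @return A data.frame of class `biopsy_table`, one row per sample, with a
#'   list-column `field_counts` of integer vectors.
#' @export
parse_biopsy_table <- function(path) {
  if (!file.exists(path)) stop_relaxo("missing-file", "no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                  colClasses = "character")
  need <- c("patient_id", "x", "y", "z", "counts", "enhancing")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_relaxo("parse", "biopsy table missing columns: ",
                paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("biopsy table ", path, " has no rows")
    out <- data.frame(patient_id = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), enhancing = logical(0))
    out$field_counts <- list()
    class(out) <- c("biopsy_table", "data.frame")
    return(out)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_relaxo("parse", "non-numeric coordinate at row ", bad[1],
                  ", column ", col)
    v
  }
  counts <- lapply(seq_len(nrow(raw)), function(i) {
    parts <- trimws(strsplit(raw$counts[i], ";", fixed = TRUE)[[1]])
    v <- suppressWarnings(as.integer(parts))
    if (length(v) < 1L || anyNA(v))
      stop_relaxo("parse", "malformed counts cell '", raw$counts[i],
                  "' at row ", i, ", column counts")
    if (any(v < 0))
      stop_relaxo("parse", "negative count at row ", i, ", column counts")
    v
  })
  out <- data.frame(patient_id = raw$patient_id, x = num("x"), y = num("y"),
                    z = num("z"),
                    enhancing = raw$enhancing %in% c("1", "TRUE", "true"),
                    stringsAsFactors = FALSE)
  out$field_counts <- counts
  class(out) <- c("biopsy_table", "data.frame")
  out
}

#' Path to a packaged data file
#' @param file filename under the package's `extdata` directory; with no
#'   argument, lists available files.
#' @return a file path (or a vector of filenames).
#' @export
relaxo_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "relaxotumor")))
  p <- system.file("extdata", file, package = "relaxotumor")
  if (p == "") stop_relaxo("missing-file", "no packaged file named ", file)
  p
}

#' Load the packaged study metadata
#'
#' Totals reported in the source study's text: pooled voxel counts of the
#' high- and low-uptake classes across the PET subcohort, and the split of
#' stereotactic samples by contrast enhancement.
#'
#' @return a list with elements `n_voxels_high`, `n_voxels_low`,
#'   `n_biopsies_enhancing`, `n_biopsies_nonenhancing`.
#' @export
study_metadata <- function() {
  yaml::read_yaml(relaxo_example("study_metadata.yaml"))
}
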