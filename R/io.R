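#' Standard cohort column schema
#'
#' Units are encoded in the column names to keep the four nutrients' units
#' (kcal, mg, mg, g) from being confused.
#'
#' @return Character vector of required column names.
#' @export
cohort_columns <- function() {
  c("id", "ffm_kg", "ei_bio_kcal", "ei_sr_kcal", "si_bio_mg", "si_sr_mg",
    "poi_bio_mg", "poi_sr_mg", "pri_bio_g", "pri_sr_g",
    "bw_kg", "wc_cm", "hr_bpm", "sbp_mmhg", "dbp_mmhg", "vo2_lmin")
}

# Outcome column lookup.
outcome_columns <- function(outcome) {
  tab <- c(bw = "bw_kg", wc = "wc_cm", hr = "hr_bpm", sbp = "sbp_mmhg",
           dbp = "dbp_mmhg", vo2 = "vo2_lmin")
  if (!all(outcome %in% names(tab))) stop("unknown outcome: ", outcome)
  unname(tab[outcome])
}

#' Read a cohort CSV
#'
#' Validates the standard column schema (extra columns are preserved) and
#' warns when the protein columns look mg-scaled (values in the thousands
#' where g/day is expected); values are never altered.
#'
#' @param path CSV file path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path)
  miss <- setdiff(cohort_columns(), names(cohort))
  if (length(miss) > 0)
    stop("cohort file missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("pri_sr_g", "pri_bio_g")) {
    v <- cohort[[col]]
    if (any(!is.na(v)) && stats::median(v, na.rm = TRUE) > 1000)
      warning("column ", col, " has mg-scale magnitudes; expected g/day ",
              "(values left untouched)")
  }
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

# FNV-1a hash of a deparsed object, as a hex string; used to stamp result
# files with the configuration they came from.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (h is kept as a double below 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write result tables as annotated TSV files
#'
#' Each table is written as `<name>.tsv` with a comment header recording the
#' package version, the seed, and a hash of the configuration, so a result
#' file identifies the run that produced it. Output bytes are deterministic
#' for fixed inputs.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @param seed seed to record in the header (may be NULL).
#' @param config configuration object to hash into the header (may be NULL).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NULL, config = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  header <- c(
    paste0("# goldbergsim ", as.character(utils::packageVersion("goldbergsim"))),
    paste0("# seed: ", if (is.null(seed)) "NA" else seed),
    paste0("# config: ", if (is.null(config)) "NA" else config_hash(config)))
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(tables[[nm]], con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a result TSV written by [write_results()]
#'
#' @param path TSV path.
#' @return Data frame (header comments skipped).
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#")
}
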