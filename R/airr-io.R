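# Clonotype table I/O: AIRR Rearrangement TSV and the MiXCR clone-export
# dialect. Only the columns the statistics need are consumed.

AIRR_COLS <- c("junction_aa", "v_call", "d_call", "j_call", "duplicate_count")
MIXCR_COLS <- c("cloneCount", "aaSeqCDR3", "allVHitsWithScore",
                "allDHitsWithScore", "allJHitsWithScore")

# MiXCR hit strings look like "TRBV5-1*00(1200),TRBV5-4*00(900)": take the
# ranked-first hit and truncate at the first '*'.
parse_mixcr_hit <- function(x) {
  first <- sub(",.*$", "", x)
  first <- sub("\\(.*$", "", first)
  sub("\\*.*$", "", first)
}

#' Read a clonotype table
#'
#' Reads one sample's clonotype table from an AIRR Rearrangement TSV
#' (columns `junction_aa`, `v_call`, `d_call`, `j_call`, `duplicate_count`)
#' or a MiXCR clone-export TSV (`cloneCount`, `aaSeqCDR3`,
#' `allVHitsWithScore`, `allDHitsWithScore`, `allJHitsWithScore`). For the
#' MiXCR dialect the ranked-first gene hit is taken and its allele/score
#' decoration stripped.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect `"airr"` or `"mixcr"`.
#' @param sample_id sample identifier; defaults to the file name stem.
#' @param patient_id,tissue optional metadata carried on the repertoire.
#' @param productive_only drop records whose CDR3 contains `*` or `_`.
#' @return a [repertoire()] with frequencies derived from read counts.
#' @export
read_airr <- function(path, dialect = c("airr", "mixcr"), sample_id = NULL,
                      patient_id = NA_character_, tissue = NA_character_,
                      productive_only = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = TRUE, showProgress = FALSE)
  required <- if (dialect == "airr") AIRR_COLS else MIXCR_COLS
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_format("file ", path, " lacks required column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  records <- if (dialect == "airr") {
    data.table::data.table(
      cdr3_aa = as.character(tab$junction_aa),
      v_call = as.character(tab$v_call),
      d_call = ifelse(is.na(tab$d_call), "", as.character(tab$d_call)),
      j_call = as.character(tab$j_call),
      read_count = as.numeric(tab$duplicate_count)
    )
  } else {
    data.table::data.table(
      cdr3_aa = as.character(tab$aaSeqCDR3),
      v_call = parse_mixcr_hit(as.character(tab$allVHitsWithScore)),
      d_call = ifelse(is.na(tab$allDHitsWithScore) | tab$allDHitsWithScore == "",
                      "", parse_mixcr_hit(as.character(tab$allDHitsWithScore))),
      j_call = parse_mixcr_hit(as.character(tab$allJHitsWithScore)),
      read_count = as.numeric(tab$cloneCount)
    )
  }
  if (nrow(records) == 0L || sum(records$read_count) <= 0) {
    stop_data("empty repertoire in ", path, ": total read count is zero")
  }
  rep <- repertoire(records, sample_id, patient_id, tissue)
  if (productive_only) rep <- filter_productive(rep)
  rep
}

#' Write a repertoire as AIRR Rearrangement TSV
#'
#' Writes `junction_aa`, `v_call`, `d_call`, `j_call`, `duplicate_count`
#' (empty `d_call` written as the empty string). Round-trips losslessly
#' through [read_airr()] on aggregated content.
#'
#' @param rep a non-empty [repertoire()].
#' @param path output path; parent directory must exist.
#' @export
write_airr <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep$records) == 0L) stop_data("cannot write an empty repertoire")
  if (!dir.exists(dirname(path))) stop_data("unwritable path: ", path)
  out <- data.table::data.table(
    junction_aa = rep$records$cdr3_aa,
    v_call = rep$records$v_call,
    d_call = rep$records$d_call,
    j_call = rep$records$j_call,
    duplicate_count = as.integer(rep$records$read_count)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a directory of AIRR files driven by a sample sheet
#'
#' The sample sheet is a CSV with columns `sample_id`, `patient_id`,
#' `tissue` and optionally `file` (defaults to `<sample_id>.tsv` in `dir`).
#'
#' @param dir directory containing AIRR TSV files.
#' @param sheet path to the sample-sheet CSV, or a data.frame.
#' @inheritParams read_airr
#' @return a [repertoire_set()].
#' @export
read_repertoire_set <- function(dir, sheet, dialect = "airr",
                                productive_only = FALSE) {
  sh <- if (is.character(sheet)) data.table::fread(sheet) else data.table::as.data.table(sheet)
  need <- c("sample_id", "patient_id", "tissue")
  missing_cols <- setdiff(need, names(sh))
  if (length(missing_cols)) {
    stop_format("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"file" %in% names(sh)) sh[, "file" := paste0(sample_id, ".tsv")]
  reps <- lapply(seq_len(nrow(sh)), function(i) {
    f <- file.path(dir, sh$file[i])
    if (!file.exists(f)) stop_data("sample ", sh$sample_id[i], ": file not found: ", f)
    read_airr(f, dialect = dialect, sample_id = sh$sample_id[i],
              patient_id = sh$patient_id[i], tissue = sh$tissue[i],
              productive_only = productive_only)
  })
  repertoire_set(reps)
}
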