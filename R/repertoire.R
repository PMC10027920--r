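# Repertoire data model.
#
# A repertoire is one sample's clonotype table. Two aggregation levels are
# meaningful throughout: a *clonotype* is a unique CDR3 amino-acid sequence;
# a *clone* is a unique (CDR3, V, D, J) combination. Raw records may repeat
# either key; aggregation is lazy and performed by aggregate_repertoire().

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
CDR3_PATTERN <- "^[ACDEFGHIKLMNPQRSTVWY*_]+$"

#' Construct a repertoire from clonotype records
#'
#' Builds the per-sample unit of all repertoire statistics: a table of
#' rearrangement records (CDR3 amino-acid sequence, V/D/J gene calls, read
#' count) plus sample metadata. Read frequencies are derived as
#' `read_count / sum(read_count)`; they always sum to 1.
#'
#' @param records data.frame with columns `cdr3_aa`, `v_call`, `j_call`,
#'   `read_count` and optionally `d_call` (empty string when the D segment is
#'   unresolved, as is common for TRBD).
#' @param sample_id,patient_id character scalars identifying the sample.
#' @param tissue tissue label (e.g. `"EAT"`, `"SAT"`, `"HEART"`); open set.
#' @return An object of class `repertoire`: a list with `sample_id`,
#'   `patient_id`, `tissue` and `records` (a data.table with derived
#'   `frequency` and a `productive` flag; CDR3s containing `*` or `_` are
#'   retained but flagged non-productive).
#' @export
repertoire <- function(records, sample_id, patient_id = NA_character_,
                       tissue = NA_character_) {
  records <- data.table::as.data.table(records)
  if (!"d_call" %in% names(records)) records[, "d_call" := ""]
  required <- c("cdr3_aa", "v_call", "d_call", "j_call", "read_count")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_format("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, required, with = FALSE]
  records[, "d_call" := ifelse(is.na(d_call), "", d_call)]
  if (nrow(records) == 0L || sum(records$read_count) <= 0) {
    stop_data("empty repertoire: total read count must be positive")
  }
  if (any(is.na(records$read_count)) || any(records$read_count < 1) ||
      any(records$read_count != round(records$read_count))) {
    stop_data("read_count must be a positive integer for every record")
  }
  bad <- !nzchar(records$cdr3_aa) | !grepl(CDR3_PATTERN, records$cdr3_aa)
  if (any(bad)) {
    stop_data("invalid cdr3_aa at record(s) ",
              paste(utils::head(which(bad), 5L), collapse = ", "),
              ": must be non-empty over the 20-letter amino-acid alphabet ",
              "plus '*' and '_'")
  }
  records[, "read_count" := as.numeric(read_count)]
  records[, "frequency" := read_count / sum(read_count)]
  records[, "productive" := !grepl("[*_]", cdr3_aa)]
  structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         tissue = as.character(tissue),
         records = records),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  agg <- aggregate_repertoire(x, "clonotype")
  cat(sprintf(
    "<repertoire> sample %s (patient %s, tissue %s): %d records, %d clonotypes, %d reads\n",
    x$sample_id, x$patient_id, x$tissue,
    nrow(x$records), nrow(agg), as.integer(sum(x$records$read_count))
  ))
  invisible(x)
}

#' Aggregate a repertoire at clonotype or clone level
#'
#' At `level = "clonotype"` records are keyed on the CDR3 amino-acid sequence
#' alone; at `level = "clone"` on the full (CDR3, V, D, J) combination, with
#' an empty `d_call` treated as a literal key component. Read counts are
#' summed and frequencies recomputed so they sum to 1.
#'
#' @param rep a [repertoire()].
#' @param level `"clonotype"` or `"clone"`.
#' @return data.table with the key column(s), `read_count` and `frequency`,
#'   sorted by the key for determinism.
#' @export
aggregate_repertoire <- function(rep, level = c("clonotype", "clone")) {
  stopifnot(inherits(rep, "repertoire"))
  level <- match.arg(level)
  keys <- if (level == "clonotype") "cdr3_aa" else c("cdr3_aa", "v_call", "d_call", "j_call")
  agg <- rep$records[, list(read_count = sum(read_count)), by = keys]
  agg[, "frequency" := read_count / sum(read_count)]
  data.table::setkeyv(agg, keys)
  agg[]
}

#' Drop non-productive or low-count records
#'
#' `filter_productive()` removes records whose CDR3 contains a stop (`*`) or
#' frameshift (`_`) marker. `filter_min_count()` removes records below a read
#' count threshold (no filtering by default anywhere in the pipeline; the
#' threshold is exposed because singleton filtering is a common repertoire
#' preprocessing choice). Frequencies are renormalized.
#'
#' @param rep a [repertoire()].
#' @param min_count minimum read count to retain.
#' @return a filtered [repertoire()].
#' @export
filter_productive <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  kept <- rep$records[rep$records$productive]
  if (nrow(kept) == 0L) stop_data("no productive records remain in ", rep$sample_id)
  repertoire(kept, rep$sample_id, rep$patient_id, rep$tissue)
}

#' @rdname filter_productive
#' @export
filter_min_count <- function(rep, min_count = 1L) {
  stopifnot(inherits(rep, "repertoire"))
  kept <- rep$records[rep$records$read_count >= min_count]
  if (nrow(kept) == 0L) stop_data("no records remain in ", rep$sample_id,
                                  " after min_count = ", min_count)
  repertoire(kept, rep$sample_id, rep$patient_id, rep$tissue)
}

#' Collect repertoires into a keyed set with a patient/tissue pairing index
#'
#' @param reps list of [repertoire()] objects with unique `sample_id`s.
#' @return class `repertoire_set`: list with `repertoires` (named by
#'   sample_id) and `pairing` (data.table patient_id / tissue / sample_id).
#' @export
repertoire_set <- function(reps) {
  stopifnot(is.list(reps), all(vapply(reps, inherits, TRUE, "repertoire")))
  ids <- vapply(reps, function(r) r$sample_id, "")
  if (anyDuplicated(ids)) {
    stop_data("duplicate sample_id in repertoire set: ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reps) <- ids
  pairing <- data.table::data.table(
    patient_id = vapply(reps, function(r) r$patient_id, ""),
    tissue = vapply(reps, function(r) r$tissue, ""),
    sample_id = ids
  )
  structure(list(repertoires = reps, pairing = pairing), class = "repertoire_set")
}

#' @export
print.repertoire_set <- function(x, ...) {
  cat(sprintf("<repertoire_set> %d samples, %d patients, tissues: %s\n",
              length(x$repertoires),
              length(unique(x$pairing$patient_id)),
              paste(sort(unique(x$pairing$tissue)), collapse = ", ")))
  invisible(x)
}

# Strip the IMGT allele suffix ("*01") so gene usage is at gene level.
strip_allele <- function(x) sub("\\*.*$", "", x)
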