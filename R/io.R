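.CORPUS_REQUIRED <- c("patient_id", "note_id", "note_type", "text")

#' Validate a corpus data.frame
#'
#' Checks the note-record schema shared by CSV and JSONL corpora: required
#' columns present, ids non-empty, `note_type` one of clinical/pathology,
#' `note_id` unique. Errors name the offending column and row. Text is left
#' byte-exact -- no whitespace normalisation happens before extraction.
#'
#' @param corpus data.frame of note records.
#' @return The validated corpus (character columns, `note_date` added as
#'   `NA` when absent).
#' @export
validate_corpus <- function(corpus) {
  if (!is.data.frame(corpus))
    stop("corpus must be a data.frame", call. = FALSE)
  for (col in .CORPUS_REQUIRED)
    if (!col %in% names(corpus))
      stop("corpus is missing required column '", col, "'", call. = FALSE)
  if (!"note_date" %in% names(corpus))
    corpus$note_date <- rep(NA_character_, nrow(corpus))
  for (col in c(.CORPUS_REQUIRED, "note_date"))
    corpus[[col]] <- as.character(corpus[[col]])
  for (col in c("patient_id", "note_id", "note_type", "text")) {
    bad <- which(is.na(corpus[[col]]) |
                   (col != "text" & !nzchar(corpus[[col]])))
    if (length(bad))
      stop("corpus column '", col, "' empty or missing at row ", bad[1],
           call. = FALSE)
  }
  bad_type <- which(!corpus$note_type %in% c("clinical", "pathology"))
  if (length(bad_type))
    stop("unknown note_type '", corpus$note_type[bad_type[1]],
         "' at row ", bad_type[1],
         " (must be 'clinical' or 'pathology')", call. = FALSE)
  dup <- which(duplicated(corpus$note_id))
  if (length(dup))
    stop("duplicate note_id '", corpus$note_id[dup[1]], "' at row ", dup[1],
         call. = FALSE)
  rownames(corpus) <- NULL
  corpus[, c("patient_id", "note_id", "note_type", "note_date", "text")]
}

#' Read a note corpus from CSV or JSONL
#'
#' CSV: UTF-8, comma-separated, quoted fields, mandatory header. JSONL: one
#' JSON object per line with the same field names (`patient_id`, `note_id`,
#' `note_type`, optional `note_date`, `text`). Both encodings of the same
#' corpus yield identical records; all records are schema-validated via
#' [validate_corpus()].
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension by
#'   default.
#' @return Validated corpus data.frame.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  if (format == "csv") {
    corpus <- utils::read.csv(path, colClasses = "character",
                              check.names = TRUE, fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(validate_corpus(data.frame(patient_id = character(),
                                        note_id = character(),
                                        note_type = character(),
                                        text = character(),
                                        stringsAsFactors = FALSE)))
    recs <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop("invalid JSON at line ", i, ": ",
                             conditionMessage(e), call. = FALSE))
      obj <- lapply(obj, function(v)
        if (is.null(v) || !length(v)) NA_character_ else as.character(v))
      as.data.frame(obj, stringsAsFactors = FALSE)
    })
    nm <- unique(unlist(lapply(recs, names)))
    recs <- lapply(recs, function(r) {
      for (col in setdiff(nm, names(r))) r[[col]] <- NA_character_
      r[, nm, drop = FALSE]
    })
    corpus <- do.call(rbind, recs)
  }
  validate_corpus(corpus)
}

#' Write a note corpus to CSV or JSONL
#'
#' @param corpus Corpus data.frame (validated on the way out).
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`; guessed from extension by default.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  corpus <- validate_corpus(corpus)
  if (format == "csv") {
    utils::write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(as.list(corpus[i, , drop = FALSE]),
                       auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Write patient-level extraction records to CSV
#'
#' @param records The `records` data.frame of a [extract_gleason()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the human-review work queue to JSONL
#'
#' One JSON object per complicated task, carrying the draft aggregate, the
#' complication reasons and per-mention evidence (note id, score as
#' written, validity, specimen call, anchor span) so a reviewer can audit
#' each triage decision.
#'
#' @param queue The `queue` element of a [extract_gleason()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_queue <- function(queue, path) {
  lines <- vapply(queue, function(q)
    as.character(jsonlite::toJSON(q, auto_unbox = TRUE, na = "null")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read/write gold task labels
#'
#' Gold labels (one row per (patient, specimen) task) travel as CSV with
#' columns `patient_id`, `specimen_type`, `P`, `S`, `T` (empty when the
#' truth is not-found), `corruption`, `expected_triage`.
#'
#' @param gold Gold data.frame (from [generate_corpus()]).
#' @param path File path.
#' @return `read_gold`: the gold data.frame; `write_gold`: `path`,
#'   invisibly.
#' @export
write_gold <- function(gold, path) {
  utils::write.csv(gold, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gold
#' @export
read_gold <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "specimen_type", "P", "S", "T",
            "corruption", "expected_triage")
  for (col in need)
    if (!col %in% names(g))
      stop("gold file missing column '", col, "'", call. = FALSE)
  g$patient_id <- as.character(g$patient_id)
  for (col in c("P", "S", "T")) g[[col]] <- as.integer(g[[col]])
  g
}

#' One-call file-to-file extraction run
#'
#' Reads a corpus, runs [extract_gleason()], writes the structured results
#' CSV and (optionally) the review-queue JSONL. Any schema error aborts
#' before partial output is written.
#'
#' @param input Corpus path (CSV or JSONL).
#' @param output Results CSV path.
#' @param queue Optional queue JSONL path.
#' @param lexicon Optional lexicon config path; bundled default otherwise.
#' @param conflict_mode Passed to [extract_gleason()].
#' @param format Corpus format, see [read_corpus()].
#' @return The `gleason_extraction` object, invisibly.
#' @export
run_extract <- function(input, output, queue = NULL, lexicon = NULL,
                        conflict_mode = c("triples", "totals"),
                        format = c("auto", "csv", "jsonl")) {
  conflict_mode <- match.arg(conflict_mode)
  lex <- if (is.null(lexicon)) default_lexicon() else load_lexicon(lexicon)
  corpus <- read_corpus(input, match.arg(format))
  res <- extract_gleason(corpus, lexicon = lex,
                         conflict_mode = conflict_mode)
  write_results(res$records, output)
  if (!is.null(queue)) write_queue(res$queue, queue)
  invisible(res)
}
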