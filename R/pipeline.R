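#' Run the full Gleason extraction pipeline over a corpus
#'
#' End-to-end composition: per-note mention extraction and specimen
#' classification ([extract_note()], in the note-type-specific module
#' order), grouping into (patient, specimen) tasks ([build_tasks()]),
#' complicated/uncomplicated triage ([triage_task()]), maximum-score
#' aggregation and record/queue assembly ([assemble_cohort()]). Fully
#' deterministic: identical corpora give identical output.
#'
#' @param corpus data.frame of notes with columns `patient_id`, `note_id`,
#'   `note_type` (`"clinical"`/`"pathology"`), optional `note_date`, and
#'   `text` (see [read_corpus()]).
#' @param lexicon A `gleason_lexicon` (default: bundled).
#' @param schedule A [window_schedule()] for clinical-mention
#'   classification.
#' @param windows A [parse_windows()] for component search.
#' @param conflict_mode `"triples"` (default) or `"totals"`; see
#'   [detect_conflicts()].
#' @return Object of class `gleason_extraction`: list with `records`
#'   (patient-level data.frame), `queue` (human-review entries), `tasks`
#'   (triaged task objects) and `n_patients`, `n_notes`, `n_mentions`.
#' @examples
#' corpus <- data.frame(
#'   patient_id = "P1", note_id = "N1", note_type = "clinical",
#'   text = "s/p PNBx: Gleason 4+3. Plan: surveillance.")
#' res <- extract_gleason(corpus)
#' res$records$biopsy_T  # 7, derived from 4+3
#' @export
extract_gleason <- function(corpus, lexicon = default_lexicon(),
                            schedule = default_window_schedule(lexicon),
                            windows = NULL,
                            conflict_mode = c("triples", "totals")) {
  conflict_mode <- match.arg(conflict_mode)
  corpus <- validate_corpus(corpus)
  mentions <- list()
  for (i in seq_len(nrow(corpus))) {
    mentions <- c(mentions,
                  extract_note(corpus[i, , drop = FALSE], lexicon,
                               schedule, windows))
  }
  tasks <- build_tasks(mentions, patients = unique(corpus$patient_id))
  tasks <- lapply(tasks, triage_task, conflict_mode = conflict_mode)
  out <- assemble_cohort(tasks)
  structure(
    list(records = out$records, queue = out$queue, tasks = tasks,
         n_patients = length(unique(corpus$patient_id)),
         n_notes = nrow(corpus), n_mentions = length(mentions)),
    class = "gleason_extraction")
}

#' @export
print.gleason_extraction <- function(x, ...) {
  n_tasks <- length(x$tasks)
  n_comp <- length(x$queue)
  cat("Gleason score extraction\n")
  cat(sprintf("  patients: %d   notes: %d   mentions: %d\n",
              x$n_patients, x$n_notes, x$n_mentions))
  cat(sprintf("  tasks: %d   complicated (-> human review): %d (%.1f%%)\n",
              n_tasks, n_comp,
              if (n_tasks) 100 * n_comp / n_tasks else 0))
  invisible(x)
}

#' @export
summary.gleason_extraction <- function(object, ...) {
  triage <- vapply(object$tasks, function(t) t$triage, character(1))
  sp <- vapply(object$tasks, function(t) t$specimen_type, character(1))
  reasons <- unlist(lapply(object$tasks, function(t) t$reasons))
  out <- list(
    n_patients = object$n_patients,
    n_tasks = length(object$tasks),
    complicated_by_specimen = table(specimen = sp, triage = triage),
    reason_counts = if (length(reasons)) table(reasons) else table(character()),
    found = c(surgery = sum(object$records$surgery_status == "extracted"),
              biopsy = sum(object$records$biopsy_status == "extracted")))
  class(out) <- "summary.gleason_extraction"
  out
}

#' @export
print.summary.gleason_extraction <- function(x, ...) {
  cat("Gleason extraction summary:", x$n_patients, "patients,",
      x$n_tasks, "tasks\n\n")
  print(x$complicated_by_specimen)
  cat("\nScores found: surgery", x$found["surgery"],
      "| biopsy", x$found["biopsy"], "\n")
  if (length(x$reason_counts)) {
    cat("\nComplication reasons:\n")
    print(x$reason_counts)
  }
  invisible(x)
}
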