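#' Group classified mentions into (patient, specimen) extraction tasks
#'
#' The unit on which triage, aggregation and accuracy are defined is the
#' *task*: one (patient, specimen_type) pair, exactly two per patient
#' (surgery and biopsy), so a cohort of n patients always yields 2n tasks
#' regardless of how many notes or mentions each patient has. Surgery- and
#' biopsy-classified mentions are routed to their task; a patient's
#' unclassified mentions are attached to both of that patient's tasks
#' (flagged `attached = TRUE`) so that triage can escalate them instead of
#' silently dropping evidence.
#'
#' @param mentions list of classified `gleason_mention` objects; each must
#'   carry a `patient_id`.
#' @param patients Character vector of all cohort patient ids (so patients
#'   with zero mentions still get their two tasks). Defaults to the ids
#'   present in `mentions`.
#' @return list of task objects (class `gleason_task`): `patient_id`,
#'   `specimen_type`, `mentions` (each with an `attached` flag), `triage`
#'   (`NA` until [triage_task()]), `reasons`.
#' @export
build_tasks <- function(mentions, patients = NULL) {
  pids <- vapply(mentions, function(m) {
    if (is.null(m$patient_id) || is.na(m$patient_id))
      stop("mention without patient_id", call. = FALSE)
    as.character(m$patient_id)
  }, character(1))
  if (is.null(patients)) patients <- unique(pids)
  patients <- sort(unique(as.character(patients)))

  tasks <- list()
  for (pid in patients) {
    pmen <- mentions[pids == pid]
    cls <- vapply(pmen, function(m) m$specimen$value, character(1))
    for (sp in c("surgery", "biopsy")) {
      own <- pmen[cls == sp]
      att <- pmen[cls == "unclassified"]
      own <- lapply(own, function(m) { m$attached <- FALSE; m })
      att <- lapply(att, function(m) { m$attached <- TRUE; m })
      tasks[[length(tasks) + 1L]] <- structure(
        list(patient_id = pid, specimen_type = sp,
             mentions = c(own, att),
             triage = NA_character_, reasons = character()),
        class = "gleason_task")
    }
  }
  tasks
}

#' @export
print.gleason_task <- function(x, ...) {
  cat(sprintf("<gleason_task> patient=%s specimen=%s mentions=%d triage=%s%s\n",
              x$patient_id, x$specimen_type, length(x$mentions),
              x$triage,
              if (length(x$reasons))
                paste0(" [", paste(x$reasons, collapse = ";"), "]") else ""))
  invisible(x)
}

# key used for conflict comparison
.triple_key <- function(triple, mode) {
  if (mode == "totals") as.character(triple$total)
  else paste(triple$primary, triple$secondary, triple$total, sep = "+")
}

#' Detect cross-note conflicts within a task
#'
#' A task is conflicting when two *valid* mentions originating from
#' different notes carry different scores -- e.g. the pathology note says
#' 4+4=8 but a clinical note says 4+3=7. Mentions within a single note
#' never conflict with themselves under this rule. By default full triples
#' are compared (so 3+4=7 vs 4+3=7 conflicts, the dominant pattern
#' differing); `mode = "totals"` relaxes the comparison to the total alone.
#'
#' @param task A `gleason_task`.
#' @param mode `"triples"` (default) or `"totals"`.
#' @return Logical: is the task conflicting?
#' @export
detect_conflicts <- function(task, mode = c("triples", "totals")) {
  mode <- match.arg(mode)
  stopifnot(inherits(task, "gleason_task"))
  vm <- Filter(function(m) m$validity == "valid", task$mentions)
  if (length(vm) < 2L) return(FALSE)
  notes <- vapply(vm, function(m) as.character(m$note_id), character(1))
  keys <- vapply(vm, function(m) .triple_key(m$triple, mode), character(1))
  for (i in seq_along(vm)[-length(vm)])
    for (j in (i + 1L):length(vm))
      if (notes[i] != notes[j] && keys[i] != keys[j]) return(TRUE)
  FALSE
}

#' Triage a task as uncomplicated or complicated
#'
#' Applies the complication criteria to one task and records the reasons:
#' * `inaccurate` -- any mention carries an impossible score (P+S != T as
#'   literally written, or a component out of range);
#' * `incomplete` -- some mention has missing components *and* no valid
#'   mention anywhere in the task supplies a complete score (a casual
#'   "Gleason 7" does not escalate a patient whose pathology spells out
#'   3+4=7);
#' * `conflicting` -- per [detect_conflicts()];
#' * `unclassified_specimen` -- the patient has a valid mention whose
#'   specimen could not be determined, and this task has no classified
#'   valid mention of its own, so the unclassified evidence would be the
#'   deciding factor.
#'
#' A task is complicated iff at least one reason applies; a task with no
#' mentions at all is uncomplicated with outcome not-found.
#'
#' @param task A `gleason_task`.
#' @param conflict_mode Passed to [detect_conflicts()].
#' @return The task with `triage` and `reasons` filled in.
#' @export
triage_task <- function(task, conflict_mode = c("triples", "totals")) {
  conflict_mode <- match.arg(conflict_mode)
  stopifnot(inherits(task, "gleason_task"))
  men <- task$mentions
  reasons <- character()
  if (length(men)) {
    validity <- vapply(men, function(m) m$validity, character(1))
    attached <- vapply(men, function(m) isTRUE(m$attached), logical(1))
    if (any(validity == "inaccurate")) reasons <- c(reasons, "inaccurate")
    if (any(validity == "incomplete") && !any(validity == "valid"))
      reasons <- c(reasons, "incomplete")
    if (detect_conflicts(task, conflict_mode))
      reasons <- c(reasons, "conflicting")
    if (any(attached & validity == "valid") &&
        !any(!attached & validity == "valid"))
      reasons <- c(reasons, "unclassified_specimen")
  }
  task$reasons <- reasons
  task$triage <- if (length(reasons)) "complicated" else "uncomplicated"
  task
}

#' Aggregate a task to its patient-level score
#'
#' The patient-level score per specimen type is the *maximum* extracted
#' score over the task's valid mentions, from pathology or clinical notes
#' alike: maximum by total T, ties broken by the higher primary pattern
#' (4+3 over 3+4, the clinically more aggressive reading), then by
#' first-seen order -- which for valid triples never matters, as equal
#' (T, P) forces an equal S. Classified mentions are preferred; a task
#' whose only valid evidence is unclassified still yields that evidence as
#' a draft (such tasks are complicated and routed to review). No valid
#' mention at all yields `"not_found"`.
#'
#' @param task A `gleason_task`.
#' @return A [gleason_triple()] or the string `"not_found"`.
#' @export
aggregate_task <- function(task) {
  stopifnot(inherits(task, "gleason_task"))
  vm <- Filter(function(m) m$validity == "valid", task$mentions)
  if (!length(vm)) return("not_found")
  attached <- vapply(vm, function(m) isTRUE(m$attached), logical(1))
  if (any(!attached)) vm <- vm[!attached]
  totals <- vapply(vm, function(m) m$triple$total, integer(1))
  prims <- vapply(vm, function(m) m$triple$primary, integer(1))
  best <- order(-totals, -prims, seq_along(vm))[1]
  vm[[best]]$triple
}

#' Assemble patient records and the human-review work queue
#'
#' Splits triaged tasks by the assisted-extraction allocation rule:
#' uncomplicated tasks are resolved automatically (their aggregate score
#' goes straight into the patient record), complicated tasks are emitted to
#' a human-review work queue while the record keeps the automated draft and
#' the complication reasons. Output is stable-ordered by patient id.
#'
#' @param tasks list of triaged `gleason_task` objects (both tasks of every
#'   patient present).
#' @return list with
#' * `records`: data.frame, one row per patient -- `patient_id`,
#'   `surgery_P/S/T`, `surgery_status` (`extracted`/`not_found`),
#'   `surgery_triage`, `surgery_reasons`, and the same four `biopsy_*`
#'   columns; draft triples are reported for complicated tasks too;
#' * `queue`: list of work-queue entries (patient_id, specimen_type,
#'   reasons, draft, evidence per mention).
#' @export
assemble_cohort <- function(tasks) {
  stopifnot(all(vapply(tasks, inherits, logical(1), "gleason_task")))
  if (any(vapply(tasks, function(t) is.na(t$triage), logical(1))))
    stop("all tasks must be triaged before assembly", call. = FALSE)
  pids <- vapply(tasks, function(t) t$patient_id, character(1))
  sps <- vapply(tasks, function(t) t$specimen_type, character(1))
  patients <- sort(unique(pids))

  queue <- list()
  rows <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    pid <- patients[k]
    row <- list(patient_id = pid)
    for (sp in c("surgery", "biopsy")) {
      idx <- which(pids == pid & sps == sp)
      if (length(idx) != 1L)
        stop("expected exactly one ", sp, " task for patient ", pid,
             call. = FALSE)
      task <- tasks[[idx]]
      agg <- aggregate_task(task)
      found <- inherits(agg, "gleason_triple")
      row[[paste0(sp, "_P")]] <- if (found) agg$primary else NA_integer_
      row[[paste0(sp, "_S")]] <- if (found) agg$secondary else NA_integer_
      row[[paste0(sp, "_T")]] <- if (found) agg$total else NA_integer_
      row[[paste0(sp, "_status")]] <- if (found) "extracted" else "not_found"
      row[[paste0(sp, "_triage")]] <- task$triage
      row[[paste0(sp, "_reasons")]] <- paste(task$reasons, collapse = ";")
      if (task$triage == "complicated") {
        queue[[length(queue) + 1L]] <- list(
          patient_id = pid, specimen_type = sp,
          reasons = task$reasons,
          draft = if (found) c(P = agg$primary, S = agg$secondary,
                               T = agg$total) else "not_found",
          evidence = lapply(task$mentions, function(m) list(
            note_id = m$note_id, validity = m$validity,
            score = format(m$triple),
            specimen = m$specimen$value,
            anchor_span = m$anchor_span)))
      }
    }
    rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    utils::read.csv(text = paste0(
      "patient_id,surgery_P,surgery_S,surgery_T,surgery_status,",
      "surgery_triage,surgery_reasons,biopsy_P,biopsy_S,biopsy_T,",
      "biopsy_status,biopsy_triage,biopsy_reasons\n"),
      stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records, queue = queue)
}
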