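# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the code paths they check.

# Naive O(text x lexicon) scan: try every lexicon surface at every offset,
# case-folded substring comparison, whole-token boundaries, then the same
# ordering contract as match_terms (start asc, longer first, better tier),
# greedy non-overlap.
brute_force_match <- function(text, category, lexicon) {
  terms <- lexicon$terms[lexicon$terms$category == category, , drop = FALSE]
  n <- nchar(text)
  is_alnum <- function(ch) nzchar(ch) && grepl("[[:alnum:]]", ch)
  hits <- list()
  for (k in seq_len(nrow(terms))) {
    surf <- tolower(terms$surface[k])
    len <- nchar(surf)
    if (len > n) next
    for (i in seq_len(n - len + 1L)) {
      if (tolower(substr(text, i, i + len - 1L)) != surf) next
      before <- if (i > 1L) substr(text, i - 1L, i - 1L) else ""
      after <- if (i + len <= n) substr(text, i + len, i + len) else ""
      if (is_alnum(before) || is_alnum(after)) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = i, end = i + len - 1L, term = terms$surface[k],
        tier = terms$tier[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      term = character(), tier = integer(),
                      stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  h <- h[order(h$start, -(h$end - h$start), h$tier), , drop = FALSE]
  keep <- logical(nrow(h)); last_end <- 0L
  for (i in seq_len(nrow(h))) {
    if (h$start[i] > last_end) { keep[i] <- TRUE; last_end <- h$end[i] }
  }
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent argmax-with-tie loop for composition -> (P, S)
oracle_patterns <- function(composition) {
  grades <- as.integer(names(composition))
  frac <- as.numeric(composition)
  top <- function(g, f) {
    best <- which(f == max(f))
    g[best][which.max(g[best])]
  }
  p <- top(grades, frac)
  if (length(grades) == 1L) return(c(P = p, S = p))
  rest <- grades != p
  s <- top(grades[rest], frac[rest])
  c(P = p, S = s)
}

# build a classified mention object directly (bypasses text extraction)
mk_mention <- function(patient_id, note_id, P = NA, S = NA, T = NA,
                       specimen = "unclassified", derived = character()) {
  triple <- complete_components(gleason_triple(P, S, T, derived))
  structure(
    list(triple = triple, anchor_span = c(1L, 7L),
         evidence_span = c(9L, 13L),
         validity = validate_triple(triple),
         note_id = note_id, note_type = "clinical",
         patient_id = patient_id,
         specimen = list(
           value = specimen,
           tier = if (specimen == "unclassified") NA_integer_ else 1L,
           span = if (specimen == "unclassified") NULL else c(20L, 25L))),
    class = "gleason_mention")
}

# triage a freshly built set of mentions into tasks
mk_tasks <- function(mentions, patients = NULL, conflict_mode = "triples") {
  lapply(build_tasks(mentions, patients), triage_task,
         conflict_mode = conflict_mode)
}

task_for <- function(tasks, patient_id, specimen_type) {
  for (t in tasks)
    if (t$patient_id == patient_id && t$specimen_type == specimen_type)
      return(t)
  stop("task not found")
}

# outcomes data.frame with prescribed stratified error counts
mk_outcomes <- function(n, triage, nlp_errors, human_errors,
                        prefix = "pt") {
  data.frame(
    patient_id = sprintf("%s%04d", prefix, seq_len(n)),
    specimen_type = "biopsy",
    triage = triage,
    nlp_correct = c(rep(FALSE, nlp_errors), rep(TRUE, n - nlp_errors)),
    human_correct = c(rep(FALSE, human_errors), rep(TRUE, n - human_errors)),
    stringsAsFactors = FALSE)
}
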