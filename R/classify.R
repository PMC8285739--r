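#' Widening search-window schedule for specimen classification
#'
#' When classifying which specimen a clinical-note Gleason mention refers
#' to, cues are first sought close to the mention; if none is found the
#' search area is broadened, ending with the whole note. The schedule is
#' the ordered list of half-window radii (characters each side of the
#' anchor midpoint), strictly increasing; an infinite final radius (the
#' whole note) is appended automatically if absent.
#'
#' @param widths Numeric vector of strictly increasing radii; `Inf` = whole
#'   note.
#' @return Numeric vector of class `window_schedule`.
#' @export
window_schedule <- function(widths = c(150, 500, Inf)) {
  widths <- as.numeric(widths)
  if (!length(widths) || anyNA(widths) || any(widths <= 0))
    stop("'widths' must be positive radii", call. = FALSE)
  if (any(diff(widths) <= 0))
    stop("'widths' must be strictly increasing", call. = FALSE)
  if (is.finite(widths[length(widths)])) widths <- c(widths, Inf)
  structure(widths, class = "window_schedule")
}

#' Default classification schedule, honouring lexicon config
#'
#' @param lexicon A `gleason_lexicon`; if its config carries
#'   `windows$classify_radii` those radii are used (whole note appended).
#' @return A [window_schedule()].
#' @export
default_window_schedule <- function(lexicon = default_lexicon()) {
  r <- lexicon$windows$classify_radii
  if (is.null(r)) window_schedule() else window_schedule(unlist(r))
}

# all specimen cues in a text: data.frame start, end, term, tier, class, mid
.specimen_cues <- function(text, lexicon) {
  s <- match_terms(text, "surgery_cue", lexicon)
  b <- match_terms(text, "biopsy_cue", lexicon)
  s$class <- rep("surgery", nrow(s))
  b$class <- rep("biopsy", nrow(b))
  cues <- rbind(s, b)
  if (nrow(cues)) cues$mid <- (cues$start + cues$end) / 2
  cues
}

.unclassified <- function() {
  list(value = "unclassified", tier = NA_integer_, span = NULL)
}

# pick the winning cue among candidates: best (lowest) tier, then nearest
# to `ref_mid`; an exact tier+distance tie between opposing classes means
# no safe call -> unclassified
.pick_cue <- function(cand, ref_mid) {
  cand <- cand[cand$tier == min(cand$tier), , drop = FALSE]
  d <- abs(cand$mid - ref_mid)
  cand <- cand[d == min(d), , drop = FALSE]
  if (length(unique(cand$class)) > 1L) return(.unclassified())
  list(value = cand$class[1],
       tier = cand$tier[1],
       span = c(cand$start[1], cand$end[1]))
}

#' Classify one clinical-note mention by its surrounding context
#'
#' Searches windows of increasing radius around the mention anchor for
#' specimen cues; within the first non-empty window the most specific
#' (lowest-tier) cue wins, ties broken by character proximity of cue
#' midpoint to anchor midpoint. A residual exact tie between a surgery and
#' a biopsy cue returns `unclassified` rather than a guess -- such mentions
#' are escalated by triage, not dropped. If every window up to the whole
#' note is empty the mention is `unclassified`.
#'
#' @param text Note text.
#' @param mention_span `c(start, end)` of the mention anchor.
#' @param lexicon A `gleason_lexicon`.
#' @param schedule A [window_schedule()].
#' @return Specimen classification: list with `value` (`"surgery"`,
#'   `"biopsy"` or `"unclassified"`), `tier`, `span`.
#' @export
classify_mention_context <- function(text, mention_span,
                                     lexicon = default_lexicon(),
                                     schedule = default_window_schedule(lexicon)) {
  stopifnot(inherits(schedule, "window_schedule"), length(mention_span) >= 2L)
  cues <- .specimen_cues(text, lexicon)
  if (!nrow(cues)) return(.unclassified())
  ref_mid <- (as.numeric(mention_span[[1]]) + as.numeric(mention_span[[2]])) / 2
  for (r in schedule) {
    sel <- cues[abs(cues$mid - ref_mid) <= r, , drop = FALSE]
    if (nrow(sel)) return(.pick_cue(sel, ref_mid))
  }
  .unclassified()  # unreachable with an Inf-terminated schedule  # nocov
}

#' Classify a whole pathology note
#'
#' A pathology report describes a single accession, so it can carry either
#' prostate-biopsy or prostate-surgery information but not both; one
#' note-level class is therefore computed from cues anywhere in the text
#' (most specific tier wins, earliest occurrence among equals) and stamped
#' on every mention subsequently extracted from that note. A tier-level tie
#' between opposing classes yields `unclassified`.
#'
#' @inheritParams classify_mention_context
#' @return Specimen classification list (see
#'   [classify_mention_context()]).
#' @export
classify_pathology_note <- function(text, lexicon = default_lexicon(),
                                    schedule = default_window_schedule(lexicon)) {
  cues <- .specimen_cues(text, lexicon)
  if (!nrow(cues)) return(.unclassified())
  best <- cues[cues$tier == min(cues$tier), , drop = FALSE]
  if (length(unique(best$class)) > 1L) return(.unclassified())
  list(value = best$class[1], tier = best$tier[1],
       span = c(best$start[1], best$end[1]))
}

#' Extract and classify all mentions of one note
#'
#' Applies the module ordering appropriate to the note type. Pathology
#' notes are classified first ([classify_pathology_note()]) and the
#' note-level class is stamped on every extracted mention. Clinical notes
#' are extracted first and each mention is then classified from its own
#' context ([classify_mention_context()]), since one clinical note may cite
#' scores from several specimen sources.
#'
#' @param note List or single-row data.frame with `text`, `note_type`
#'   (`"clinical"` or `"pathology"`), and optionally `note_id`,
#'   `patient_id`.
#' @param lexicon A `gleason_lexicon`.
#' @param schedule A [window_schedule()] for clinical mentions.
#' @param windows A [parse_windows()] (default from lexicon config).
#' @return list of classified `gleason_mention` objects.
#' @export
extract_note <- function(note, lexicon = default_lexicon(),
                         schedule = default_window_schedule(lexicon),
                         windows = NULL) {
  ntype <- as.character(note$note_type)
  if (length(ntype) != 1L || is.na(ntype) ||
      !ntype %in% c("clinical", "pathology"))
    stop("note_type must be 'clinical' or 'pathology', got '",
         paste(ntype, collapse = ","), "'", call. = FALSE)
  text <- as.character(note$text)
  if (ntype == "pathology") {
    cls <- classify_pathology_note(text, lexicon, schedule)
    mentions <- extract_mentions(note, lexicon, windows)
    lapply(mentions, function(m) { m$specimen <- cls; m })
  } else {
    mentions <- extract_mentions(note, lexicon, windows)
    lapply(mentions, function(m) {
      m$specimen <- classify_mention_context(text, m$anchor_span,
                                             lexicon, schedule)
      m
    })
  }
}
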