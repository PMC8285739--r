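#' Component-search window sizes
#'
#' After an anchor hit ("Gleason", "GS", ...) the extractor scans a bounded
#' stretch of text for the numeric components: first `after` characters
#' following the anchor, then -- only if that yields nothing -- `before`
#' characters preceding it. Both stretches stop at sentence boundaries
#' (a period followed by whitespace) and never cross a neighbouring anchor,
#' so adjacent mentions cannot steal each other's digits.
#'
#' @param after Characters scanned after the anchor (default 60).
#' @param before Characters scanned before the anchor (default 30).
#' @return A list of class `parse_windows`.
#' @export
parse_windows <- function(after = 60L, before = 30L) {
  after <- as.integer(after); before <- as.integer(before)
  stopifnot(length(after) == 1L, length(before) == 1L,
            !is.na(after), !is.na(before), after >= 1L, before >= 0L)
  structure(list(after = after, before = before), class = "parse_windows")
}

# windows from a lexicon config when present, package defaults otherwise
.windows_from_lexicon <- function(lexicon) {
  w <- lexicon$windows
  parse_windows(
    after  = if (!is.null(w$parse_after)) w$parse_after else 60L,
    before = if (!is.null(w$parse_before)) w$parse_before else 30L
  )
}

#' Locate Gleason anchors in a note
#'
#' Thin wrapper over [match_terms()] restricted to the `gleason_anchor`
#' category; one anchor per downstream mention, ordered by offset.
#'
#' @param text Note text.
#' @param lexicon A `gleason_lexicon`.
#' @return data.frame of anchor spans (`start`, `end`, `term`, `tier`).
#' @export
find_mentions <- function(text, lexicon) {
  match_terms(text, "gleason_anchor", lexicon)
}

# Surface grammars for the numeric components, in precedence order.
# (a) "P+S=T"    fully specified
# (b) "P+S"      pair, total derivable; must not fire inside "(P+S)" or
#                before "=" so it cannot mask an explicitly written total
# (c) "T (P+S)"  parenthesised components after the total
# (d) lone total in 6-10; guards reject digits glued to / - % . (dates,
#                ranges, percentages)
# (e) lone pattern 3-5 when the anchor is qualified by "primary"/"secondary"
#                just before it ("Primary GS was 4")
.G_NUM_A <- "(?<!\\d)(\\d{1,2})[ \t]*\\+[ \t]*(\\d{1,2})[ \t]*=[ \t]*(\\d{1,2})(?!\\d)"
.G_NUM_B <- "(?<![\\d(])(\\d{1,2})[ \t]*\\+[ \t]*(\\d{1,2})(?![ \t]*[=+]|\\d)"
.G_NUM_C <- "(?<!\\d)(\\d{1,2})[ \t]*\\([ \t]*(\\d{1,2})[ \t]*\\+[ \t]*(\\d{1,2})[ \t]*\\)"
.G_NUM_D <- "(?<![\\d/+=.-])(10|[6-9])(?![\\d/%+=-])"
.G_NUM_E <- "(?<![\\d/+=.-])([3-5])(?![\\d/%+=-])"

# first match of a pattern inside window w; returns groups + span or NULL
.first_match <- function(w, pattern) {
  m <- regexpr(pattern, w, perl = TRUE)
  if (m[1] == -1L) return(NULL)
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  if (is.null(cs)) {  # compute capture groups via regmatches fallback
    stop("pattern without capture groups")  # nocov
  }
  groups <- vapply(seq_along(cs), function(j) {
    substr(w, cs[j], cs[j] + cl[j] - 1L)
  }, character(1))
  list(groups = as.integer(groups),
       start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

# ensure capture positions are returned by regexpr
.rx <- function(pattern) pattern  # patterns already use perl = TRUE capture

# scan one window (already sliced from text, with offset) for the grammars
.scan_window <- function(w, offset, qualifier) {
  if (!nzchar(w)) return(NULL)
  span_of <- function(m) c(offset + m$start - 1L, offset + m$end - 1L)

  m <- .first_match(w, .G_NUM_A)
  if (!is.null(m))
    return(list(triple = gleason_triple(m$groups[1], m$groups[2], m$groups[3]),
                span = span_of(m)))
  m <- .first_match(w, .G_NUM_B)
  if (!is.null(m))
    return(list(triple = gleason_triple(m$groups[1], m$groups[2], NA),
                span = span_of(m)))
  m <- .first_match(w, .G_NUM_C)
  if (!is.null(m))
    return(list(triple = gleason_triple(m$groups[2], m$groups[3], m$groups[1]),
                span = span_of(m)))
  m <- .first_match(w, .G_NUM_D)
  if (!is.null(m))
    return(list(triple = gleason_triple(NA, NA, m$groups[1]),
                span = span_of(m)))
  if (!is.na(qualifier)) {
    m <- .first_match(w, .G_NUM_E)
    if (!is.null(m)) {
      tr <- if (qualifier == "primary")
        gleason_triple(primary = m$groups[1])
      else
        gleason_triple(secondary = m$groups[1])
      return(list(triple = tr, span = span_of(m)))
    }
  }
  NULL
}

#' Parse the Gleason components around one anchor
#'
#' Scans a bounded window after (then, failing that, before) an anchor hit
#' for the supported surface grammars, returning the first that matches in
#' precedence order: (a) `P+S=T`, (b) `P+S`, (c) `T (P+S)`, (d) a lone
#' total in 6-10, and finally a lone pattern in 3-5 when the anchor is
#' immediately qualified by "primary" or "secondary" (as in "Primary GS
#' was 4"). Digits are read verbatim -- "3+4=8" yields total 8, never a
#' corrected 7 -- and a lone integer outside 6-10 next to an unqualified
#' anchor is ignored so dates and percentages are not mistaken for scores.
#' Hyphenated ranges ("Gleason 6-7") are deliberately not parsed.
#'
#' Windows stop at sentence boundaries (period + whitespace) and at the
#' `limit_*` offsets, which [extract_mentions()] sets to the neighbouring
#' anchors' edges.
#'
#' @param text Note text.
#' @param anchor Integer vector `c(start, end)` of the anchor span, as
#'   produced by [find_mentions()] on the same text.
#' @param windows A [parse_windows()].
#' @param limit_before,limit_after Hard character offsets the window must
#'   not cross (defaults: start and end of `text`).
#' @return list with `triple` (a [gleason_triple()], possibly fully absent)
#'   and `evidence_span` (`c(start, end)` or `NULL` when no digits found).
#' @export
parse_components <- function(text, anchor, windows = parse_windows(),
                             limit_before = 1L,
                             limit_after = nchar(text)) {
  stopifnot(is.character(text), length(text) == 1L,
            length(anchor) >= 2L, inherits(windows, "parse_windows"))
  a_start <- as.integer(anchor[[1]]); a_end <- as.integer(anchor[[2]])
  n <- nchar(text)

  # qualifier immediately before the anchor ("Primary GS ...")
  pre <- substr(text, max(1L, a_start - 20L), a_start - 1L)
  qm <- regexpr("(primary|secondary)[^[:alnum:]]{0,3}$", pre,
                perl = TRUE, ignore.case = TRUE)
  qualifier <- if (qm[1] == -1L) NA_character_ else {
    tolower(sub("[^[:alnum:]]*$", "",
                substr(pre, qm, qm + attr(qm, "match.length") - 1L)))
  }

  # after-window: anchor end .. +after, clipped at limit and sentence end
  wa_start <- a_end + 1L
  wa_end <- min(a_end + windows$after, limit_after, n)
  res <- NULL
  if (wa_start <= wa_end) {
    w <- substr(text, wa_start, wa_end)
    sb <- regexpr("\\.[[:space:]]", w, perl = TRUE)
    if (sb[1] != -1L) w <- substr(w, 1L, sb[1])
    res <- .scan_window(w, wa_start, qualifier)
  }
  # before-window fallback: -before .. anchor start, clipped likewise
  if (is.null(res) && windows$before > 0L) {
    wb_start <- max(1L, a_start - windows$before, limit_before)
    wb_end <- a_start - 1L
    if (wb_start <= wb_end) {
      w <- substr(text, wb_start, wb_end)
      sbs <- gregexpr("\\.[[:space:]]", w, perl = TRUE)[[1]]
      if (sbs[1] != -1L) {  # start after the last sentence boundary
        cut <- sbs[length(sbs)] + 1L
        w <- substr(w, cut + 1L, nchar(w))
        wb_start <- wb_start + cut
      }
      res <- .scan_window(w, wb_start, qualifier)
    }
  }
  if (is.null(res))
    list(triple = gleason_triple(), evidence_span = NULL)
  else
    list(triple = res$triple, evidence_span = res$span)
}

#' Extract all Gleason mentions from one note
#'
#' The extractor-module composition: [find_mentions()] locates anchors,
#' [parse_components()] reads the adjacent components, a missing third
#' component is filled by [complete_components()] via P + S = T, and
#' [validate_triple()] stamps each mention `valid`, `inaccurate` or
#' `incomplete`. One mention per anchor, in text order; deterministic.
#'
#' @param note A list or single-row data.frame with at least `text`;
#'   `note_id`, `patient_id`, `note_type` are carried through when present.
#' @param lexicon A `gleason_lexicon` (default: bundled).
#' @param windows A [parse_windows()]; defaults come from the lexicon
#'   config when it carries window sizes.
#' @return list of mention objects (class `gleason_mention`): `triple`,
#'   `anchor_span`, `evidence_span`, `validity`, `note_id`, `note_type`,
#'   `patient_id`, and a `specimen` slot filled later by the classifier.
#' @examples
#' m <- extract_mentions(list(text = "Gleason 4+3 in the cores."))
#' m[[1]]$triple  # 4+3=7, total derived
#' @export
extract_mentions <- function(note, lexicon = default_lexicon(),
                             windows = NULL) {
  text <- as.character(note$text)
  stopifnot(length(text) == 1L, !is.na(text))
  if (is.null(windows)) windows <- .windows_from_lexicon(lexicon)
  anchors <- find_mentions(text, lexicon)
  if (!nrow(anchors)) return(list())
  field <- function(nm) if (is.null(note[[nm]])) NA_character_
                        else as.character(note[[nm]])
  lapply(seq_len(nrow(anchors)), function(i) {
    lim_after <- if (i < nrow(anchors)) anchors$start[i + 1L] - 1L
                 else nchar(text)
    lim_before <- if (i > 1L) anchors$end[i - 1L] + 1L else 1L
    parsed <- parse_components(text, c(anchors$start[i], anchors$end[i]),
                               windows, lim_before, lim_after)
    triple <- complete_components(parsed$triple)
    structure(
      list(triple = triple,
           anchor_span = c(anchors$start[i], anchors$end[i]),
           evidence_span = parsed$evidence_span,
           validity = validate_triple(triple),
           note_id = field("note_id"),
           note_type = field("note_type"),
           patient_id = field("patient_id"),
           specimen = list(value = "unclassified", tier = NA_integer_,
                           span = NULL)),
      class = "gleason_mention")
  })
}

#' @export
print.gleason_mention <- function(x, ...) {
  cat(sprintf("<gleason_mention> %s (%s) specimen=%s anchor=[%d,%d]\n",
              format(x$triple), x$validity, x$specimen$value,
              x$anchor_span[1], x$anchor_span[2]))
  invisible(x)
}
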