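#' @keywords internal
.LEXICON_CATEGORIES <- c("gleason_anchor", "surgery_cue", "biopsy_cue")

#' Load a lexicon from a configuration file or list
#'
#' A lexicon is the configurable heart of the extractor: a versioned list of
#' surface terms, each tagged with a category (`gleason_anchor` marks a
#' score mention; `surgery_cue` / `biopsy_cue` classify the specimen) and a
#' priority tier (1 = most specific, wins over higher tier numbers). The
#' config is a YAML or JSON document with top-level keys `version` and
#' `terms`, each term an object `{surface, category, tier}`; `tier` defaults
#' to 2 when omitted, tier 1 being reserved for the most specific cues. An
#' optional `windows` key carries parsing/classification window sizes (see
#' [parse_windows()], [window_schedule()]).
#'
#' @param source Path to a `.yaml`/`.yml`/`.json` file, or an already-parsed
#'   list with the same structure.
#' @return An object of class `gleason_lexicon`: list with `version`
#'   (character), `terms` (data.frame: surface, category, tier) and
#'   `windows` (list or NULL).
#' @examples
#' lex <- load_lexicon(list(version = "x", terms = list(
#'   list(surface = "Gleason", category = "gleason_anchor"),
#'   list(surface = "prostatectomy", category = "surgery_cue", tier = 1),
#'   list(surface = "biopsy", category = "biopsy_cue"))))
#' @export
load_lexicon <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source))
      stop("lexicon config file not found: ", source, call. = FALSE)
    cfg <- if (grepl("\\.json$", source, ignore.case = TRUE))
      jsonlite::fromJSON(source, simplifyDataFrame = FALSE)
    else
      yaml::read_yaml(source)
  } else if (is.list(source)) {
    cfg <- source
  } else {
    stop("'source' must be a file path or a list", call. = FALSE)
  }
  if (is.null(cfg$terms) || !length(cfg$terms))
    stop("lexicon config has no 'terms' entry", call. = FALSE)

  rows <- lapply(seq_along(cfg$terms), function(i) {
    tm <- cfg$terms[[i]]
    surface <- tm$surface
    category <- tm$category
    tier <- if (is.null(tm$tier)) 2L else tm$tier
    if (is.null(surface) || !nzchar(trimws(as.character(surface))))
      stop("lexicon term #", i, ": empty or missing 'surface'", call. = FALSE)
    if (is.null(category) || !category %in% .LEXICON_CATEGORIES)
      stop("lexicon term #", i, " ('", surface, "'): unknown category '",
           if (is.null(category)) "<missing>" else category,
           "' (must be one of ", paste(.LEXICON_CATEGORIES, collapse = ", "),
           ")", call. = FALSE)
    tier <- suppressWarnings(as.integer(tier))
    if (is.na(tier) || tier < 1L)
      stop("lexicon term #", i, " ('", surface,
           "'): 'tier' must be an integer >= 1", call. = FALSE)
    data.frame(surface = as.character(surface), category = category,
               tier = tier, stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, rows)
  dup <- duplicated(terms[, c("surface", "category")])
  if (any(dup))
    stop("duplicate lexicon (surface, category) pair: '",
         terms$surface[dup][1], "' / ", terms$category[dup][1],
         call. = FALSE)
  for (cat in .LEXICON_CATEGORIES)
    if (!any(terms$category == cat))
      stop("lexicon must contain at least one term of category '", cat, "'",
           call. = FALSE)
  structure(
    list(version = as.character(if (is.null(cfg$version)) "unversioned"
                                else cfg$version),
         terms = terms,
         windows = cfg$windows),
    class = "gleason_lexicon"
  )
}

# cache for the bundled lexicon (content is deterministic)
.lexicon_cache <- new.env(parent = emptyenv())

#' The bundled default lexicon
#'
#' Returns the expert-style lexicon shipped with the package
#' (`inst/extdata/default_lexicon.yaml`): Gleason anchors such as "Gleason"
#' and "GS", specific tier-1 specimen cues such as "prostatectomy", "RRP"
#' and "PNBx", and less specific tier-2 cues such as "pathologic stage" or
#' "biopsy". Deterministic: every call returns identical content.
#'
#' @return A `gleason_lexicon`.
#' @export
default_lexicon <- function() {
  if (is.null(.lexicon_cache$default)) {
    path <- system.file("extdata", "default_lexicon.yaml",
                        package = "gleasonr", mustWork = TRUE)
    .lexicon_cache$default <- load_lexicon(path)
  }
  .lexicon_cache$default
}

#' @export
print.gleason_lexicon <- function(x, ...) {
  cat("<gleason_lexicon> version", x$version, "-",
      nrow(x$terms), "terms\n")
  print(table(x$terms$category))
  invisible(x)
}

# escape a literal surface for use inside a PCRE pattern
.regex_escape <- function(s) gsub("([][{}()+*^$|\\\\?.&~#-])", "\\\\\\1", s)

#' Find lexicon term occurrences in text
#'
#' Case-insensitive, whole-token matching of every lexicon surface of one
#' category against raw note text: a hit must not be flanked by alphanumeric
#' characters on either side (so "GS" never fires inside "drugs"). Returns
#' all non-overlapping occurrences ordered by start offset; where surfaces
#' overlap (e.g. "Gleason score" and "Gleason" at the same position) the
#' longer match wins. Spans are 1-based inclusive character intervals into
#' the raw text, so `substr(text, start, end)` recovers the matched slice.
#'
#' @param text A single note text string (may be empty).
#' @param category One of `"gleason_anchor"`, `"surgery_cue"`, `"biopsy_cue"`.
#' @param lexicon A `gleason_lexicon`.
#' @return data.frame with columns `start`, `end`, `term` (the lexicon
#'   surface), `tier`; zero rows when nothing matches.
#' @examples
#' match_terms("gleason score 7", "gleason_anchor", default_lexicon())
#' @export
match_terms <- function(text, category, lexicon) {
  stopifnot(inherits(lexicon, "gleason_lexicon"),
            is.character(text), length(text) == 1L)
  category <- match.arg(category, .LEXICON_CATEGORIES)
  empty <- data.frame(start = integer(), end = integer(),
                      term = character(), tier = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  terms <- lexicon$terms[lexicon$terms$category == category, , drop = FALSE]
  if (!nrow(terms)) return(empty)

  hits <- empty
  for (k in seq_len(nrow(terms))) {
    pat <- paste0("(?<![[:alnum:]])", .regex_escape(terms$surface[k]),
                  "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    hits <- rbind(hits, data.frame(
      start = as.integer(m), end = as.integer(m) + len - 1L,
      term = terms$surface[k], tier = terms$tier[k],
      stringsAsFactors = FALSE))
  }
  if (!nrow(hits)) return(empty)
  # prefer earlier start, then longer match, then better (lower) tier;
  # greedily keep non-overlapping spans
  hits <- hits[order(hits$start, -(hits$end - hits$start), hits$tier), ,
               drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
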