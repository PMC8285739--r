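#' Gleason component triple
#'
#' A Gleason score is reported as three components: the primary pattern P
#' (most prevalent histologic grade, 3-5), the secondary pattern S (second
#' most prevalent grade, 3-5), and the total T = P + S (6-10). Notes often
#' state only two of the three; the third is recoverable from the identity
#' P + S = T. `gleason_triple()` builds a possibly partial triple and keeps
#' book on which components were *derived* (computed from the identity)
#' rather than read verbatim from text. Components are stored exactly as
#' read -- an out-of-range or arithmetically impossible value is never
#' repaired here; [validate_triple()] flags it instead.
#'
#' @param primary,secondary,total Integer component values, or `NA` when the
#'   component was not found in text.
#' @param derived Character vector naming which of `"primary"`,
#'   `"secondary"`, `"total"` were computed via P + S = T rather than read.
#' @return An object of class `gleason_triple`: a list with elements
#'   `primary`, `secondary`, `total` (integer or `NA`) and `derived`.
#' @seealso [complete_components()], [validate_triple()]
#' @examples
#' gleason_triple(primary = 3, secondary = 4, total = 7)
#' gleason_triple(primary = 4)  # partial: only P was documented
#' @export
gleason_triple <- function(primary = NA, secondary = NA, total = NA,
                           derived = character()) {
  as_component <- function(x, what) {
    if (length(x) != 1L)
      stop("'", what, "' must be a single value", call. = FALSE)
    if (is.na(x)) return(NA_integer_)
    xi <- suppressWarnings(as.integer(x))
    if (is.na(xi) || xi != x)
      stop("'", what, "' must be an integer or NA, got ", x, call. = FALSE)
    xi
  }
  if (!is.character(derived) ||
      !all(derived %in% c("primary", "secondary", "total")))
    stop("'derived' must name components: primary/secondary/total",
         call. = FALSE)
  structure(
    list(primary   = as_component(primary, "primary"),
         secondary = as_component(secondary, "secondary"),
         total     = as_component(total, "total"),
         derived   = unique(derived)),
    class = "gleason_triple"
  )
}

#' @export
format.gleason_triple <- function(x, ...) {
  f <- function(v) if (is.na(v)) "?" else as.character(v)
  sprintf("%s+%s=%s", f(x$primary), f(x$secondary), f(x$total))
}

#' @export
print.gleason_triple <- function(x, ...) {
  cat("<gleason_triple> ", format(x), sep = "")
  if (length(x$derived))
    cat("  [derived: ", paste(x$derived, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Is every component of a triple present?
#'
#' @param triple A [gleason_triple()].
#' @return `TRUE` if primary, secondary and total are all non-missing.
#' @export
is_complete_triple <- function(triple) {
  stopifnot(inherits(triple, "gleason_triple"))
  !anyNA(c(triple$primary, triple$secondary, triple$total))
}

#' Do two triples carry the same score?
#'
#' Compares the three components positionally; component order matters, so
#' 4+3=7 and 3+4=7 are *different* scores (they imply different dominant
#' patterns). `NA` components must match as `NA`.
#'
#' @param a,b [gleason_triple()] objects.
#' @return Logical scalar.
#' @export
triple_equal <- function(a, b) {
  stopifnot(inherits(a, "gleason_triple"), inherits(b, "gleason_triple"))
  identical(c(a$primary, a$secondary, a$total),
            c(b$primary, b$secondary, b$total))
}

#' Complete a partial triple via P + S = T
#'
#' When a note documents exactly two of the three Gleason components, the
#' third is determined by the identity P + S = T (e.g. T = 7 is derived from
#' P = 4 and S = 3). The derived component is recorded in the triple's
#' `derived` set so that downstream validation can distinguish a read
#' arithmetic error (3+4=8 written in the note) from a derivation. A triple
#' with fewer than two known components is underdetermined and returned
#' unchanged, as is a complete triple: a value read from text is never
#' overwritten. The operation is idempotent.
#'
#' Derivation applies the identity blindly; range checking is
#' [validate_triple()]'s job. Deriving S = 6 from P = 3, T = 9 is expected
#' behaviour and will be flagged inaccurate downstream.
#'
#' @param triple A [gleason_triple()], possibly partial.
#' @return A [gleason_triple()] with the third component filled in when
#'   exactly two were present.
#' @examples
#' complete_components(gleason_triple(primary = 4, secondary = 3))
#' @export
complete_components <- function(triple) {
  stopifnot(inherits(triple, "gleason_triple"))
  present <- !is.na(c(primary   = triple$primary,
                      secondary = triple$secondary,
                      total     = triple$total))
  if (sum(present) != 2L) return(triple)
  missing_field <- names(present)[!present]
  value <- switch(missing_field,
    total     = triple$primary + triple$secondary,
    secondary = triple$total - triple$primary,
    primary   = triple$total - triple$secondary
  )
  triple[[missing_field]] <- as.integer(value)
  triple$derived <- unique(c(triple$derived, missing_field))
  triple
}

# Component ranges fixed by the grading system: patterns 3-5, totals 6-10.
.GS_PRIMARY_RANGE   <- c(3L, 5L)
.GS_SECONDARY_RANGE <- c(3L, 5L)
.GS_TOTAL_RANGE     <- c(6L, 10L)

#' Validate a (completed) triple
#'
#' Classifies a triple, after [complete_components()] has been applied, as:
#' * `"incomplete"` -- at least one component still missing (fewer than two
#'   were recoverable from text);
#' * `"inaccurate"` -- all components present but the score is impossible:
#'   any component out of range (P, S in 3-5, T in 6-10), or all three read
#'   verbatim and P + S != T (e.g. the note literally says "3+4=8");
#' * `"valid"` -- complete, in range, arithmetically consistent.
#'
#' @param triple A [gleason_triple()].
#' @return One of `"valid"`, `"inaccurate"`, `"incomplete"`.
#' @examples
#' validate_triple(gleason_triple(3, 4, 7))  # "valid"
#' validate_triple(gleason_triple(3, 4, 8))  # "inaccurate"
#' validate_triple(gleason_triple(primary = 4))  # "incomplete"
#' @export
validate_triple <- function(triple) {
  stopifnot(inherits(triple, "gleason_triple"))
  if (!is_complete_triple(triple)) return("incomplete")
  in_range <- function(x, r) x >= r[1] && x <= r[2]
  if (!in_range(triple$primary, .GS_PRIMARY_RANGE) ||
      !in_range(triple$secondary, .GS_SECONDARY_RANGE) ||
      !in_range(triple$total, .GS_TOTAL_RANGE))
    return("inaccurate")
  all_read <- length(triple$derived) == 0L
  if (all_read && triple$primary + triple$secondary != triple$total)
    return("inaccurate")
  "valid"
}
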