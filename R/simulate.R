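#' Assign primary/secondary patterns from a specimen grade composition
#'
#' The primary and secondary Gleason patterns are, by definition, the first
#' and second most prevalent histologic grades in a specimen. Given a grade
#' composition (fractions over grades 3-5 summing to one) this returns
#' `(P, S)`: e.g. 15% grade 3 / 55% grade 4 / 30% grade 5 gives P = 4,
#' S = 5. A single-grade specimen repeats the grade (S = P). Exact ties are
#' broken in favour of the higher grade taking the contested (more
#' prominent) slot, so 50/50 grade 3/4 gives P = 4, S = 3.
#'
#' @param composition Named numeric vector: names are grades (`"3"`, `"4"`,
#'   `"5"`), values positive fractions summing to 1.
#' @return Named integer vector `c(P = , S = )`.
#' @examples
#' assign_patterns_from_composition(c("3" = 0.15, "4" = 0.55, "5" = 0.30))
#' @export
assign_patterns_from_composition <- function(composition) {
  if (is.null(names(composition)) || !is.numeric(composition))
    stop("'composition' must be a named numeric vector", call. = FALSE)
  grades <- suppressWarnings(as.integer(names(composition)))
  if (anyNA(grades) || !all(grades %in% 3:5))
    stop("composition grades must be 3, 4 or 5", call. = FALSE)
  if (anyDuplicated(grades))
    stop("duplicate grade in composition", call. = FALSE)
  frac <- as.numeric(composition)
  if (any(frac <= 0))
    stop("composition fractions must be positive", call. = FALSE)
  if (abs(sum(frac) - 1) > 1e-6)
    stop("composition fractions must sum to 1 (got ", sum(frac), ")",
         call. = FALSE)
  ord <- order(-frac, -grades)
  p <- grades[ord[1]]
  s <- if (length(grades) == 1L) p else grades[ord[2]]
  c(P = p, S = s)
}

#' Parameters for the synthetic note generator
#'
#' Bundles and validates the knobs of [generate_corpus()]. Defaults are
#' fixed at the cohort conditions the generator emulates: an average of
#' 18.2 clinical and 3.6 pathology notes per patient, a 4.85% per-task
#' complication rate, surgery documentation for 56% of patients, and a
#' uniform split across the three corruption kinds (their individual
#' frequencies are not known, only the aggregate). The seed is mandatory --
#' there is no wall-clock default -- and fully determines the corpus.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer master seed (mandatory).
#' @param complication_rate Per-task probability of an injected corruption.
#' @param kind_split Named probabilities over
#'   `inaccurate_sum`/`missing_component`/`cross_note_conflict`, summing
#'   to 1.
#' @param notes_per_patient Named mean note counts, `c(clinical = ,
#'   pathology = )`.
#' @param surgery_prob Probability a patient has a documented surgery
#'   score (biopsy scores are always documented).
#' @param upgrade_prob Probability a documented surgery score is strictly
#'   upgraded (higher total) relative to the biopsy score, emulating
#'   pathologic upgrading; otherwise the surgery score equals the biopsy
#'   score. Surgery totals never fall below biopsy totals.
#' @param echo_prob Probability a clean documented score is additionally
#'   echoed in a clinical note (same triple, possibly a terser surface
#'   form).
#' @param template_bank Template bank (see [default_template_bank()]).
#' @return Validated list of class `generator_params`.
#' @export
generator_params <- function(n_patients, seed,
                             complication_rate = 0.0485,
                             kind_split = c(inaccurate_sum = 1/3,
                                            missing_component = 1/3,
                                            cross_note_conflict = 1/3),
                             notes_per_patient = c(clinical = 18.2,
                                                   pathology = 3.6),
                             surgery_prob = 0.56,
                             upgrade_prob = 0.35,
                             echo_prob = 0.6,
                             template_bank = default_template_bank()) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory for the generator", call. = FALSE)
  n_patients <- as.integer(n_patients)
  stopifnot(length(n_patients) == 1L, !is.na(n_patients), n_patients >= 1L)
  prob_ok <- function(p) length(p) == 1L && !is.na(p) && p >= 0 && p <= 1
  if (!prob_ok(complication_rate) || !prob_ok(surgery_prob) ||
      !prob_ok(upgrade_prob) || !prob_ok(echo_prob))
    stop("rates/probabilities must be single values in [0, 1]",
         call. = FALSE)
  kinds <- c("inaccurate_sum", "missing_component", "cross_note_conflict")
  if (!setequal(names(kind_split), kinds) ||
      any(kind_split < 0) || abs(sum(kind_split) - 1) > 1e-6)
    stop("'kind_split' must be probabilities over ",
         paste(kinds, collapse = "/"), " summing to 1", call. = FALSE)
  if (!all(c("clinical", "pathology") %in% names(notes_per_patient)) ||
      any(notes_per_patient < 0))
    stop("'notes_per_patient' needs non-negative means for clinical and ",
         "pathology", call. = FALSE)
  if (!length(template_bank))
    stop("empty template bank", call. = FALSE)
  structure(list(
    n_patients = n_patients,
    seed = as.integer(seed),
    complication_rate = complication_rate,
    kind_split = kind_split[kinds],
    notes_per_patient = notes_per_patient,
    surgery_prob = surgery_prob,
    upgrade_prob = upgrade_prob,
    echo_prob = echo_prob,
    template_bank = template_bank), class = "generator_params")
}

#' The bundled note template bank
#'
#' Plain-text templates with `{P}`, `{S}`, `{T}`, `{MO}`, `{YR}`
#' placeholder slots, tagged with note type, specimen and the surface
#' grammar they render: (a) `P+S=T`, (b) `P+S`, (c) `T (P+S)`, (d) lone
#' total. Grammar-d templates state only the total and are used as echo
#' notes, never as a task's sole score evidence. Filler templates carry no
#' Gleason content and pad per-patient note counts with realistic
#' distractor text. Users can extend the bank (e.g. with local dialects)
#' and pass it through [generator_params()].
#'
#' @return list of template entries (`note_type`, `specimen`, `grammar`,
#'   `text`); filler entries have `specimen = NA` and `grammar = "none"`.
#' @export
default_template_bank <- function() {
  tpl <- function(note_type, specimen, grammar, text)
    list(note_type = note_type, specimen = specimen, grammar = grammar,
         text = text)
  list(
    # pathology, score-bearing
    tpl("pathology", "biopsy", "a",
        "PROSTATE, RIGHT AND LEFT, NEEDLE BIOPSY: ADENOCARCINOMA, Gleason score {P}+{S}={T}, involving 3 of 12 cores."),
    tpl("pathology", "biopsy", "c",
        "Prostate needle biopsy ({MO}/{YR}). DIAGNOSIS: prostatic adenocarcinoma, Gleason {T} ({P}+{S})."),
    tpl("pathology", "surgery", "a",
        "PROSTATE, RADICAL PROSTATECTOMY: ADENOCARCINOMA, Gleason score {P}+{S}={T}. Surgical margins negative."),
    tpl("pathology", "surgery", "c",
        "Radical retropubic prostatectomy specimen: adenocarcinoma, Gleason {T} ({P}+{S}). Pathologic stage pT2c."),
    # clinical, score-bearing
    tpl("clinical", "biopsy", "a",
        "Follow-up visit. PNBx {MO}/{YR} showed Gleason {P}+{S}={T}. PSA stable."),
    tpl("clinical", "biopsy", "c",
        "Prostate biopsy revealed GS {T} ({P}+{S}). Discussed management options."),
    tpl("clinical", "biopsy", "b",
        "Seen in urology clinic. Core biopsy Gleason score {P}+{S}. Will repeat PSA in 3 months."),
    tpl("clinical", "biopsy", "d",
        "Known prostate cancer, Gleason {T} on core biopsy, under active surveillance."),
    tpl("clinical", "surgery", "a",
        "History: s/p RRP in {YR}, surgical pathology with Gleason score {P}+{S}={T}."),
    tpl("clinical", "surgery", "b",
        "s/p radical prostatectomy, final Gleason {P}+{S}. Continues to do well."),
    tpl("clinical", "surgery", "d",
        "Status post prostatectomy {YR}, Gleason {T}, no evidence of recurrence."),
    # filler (no Gleason content)
    tpl("clinical", NA, "none",
        "Patient seen in follow-up today. No new complaints. PSA reviewed and stable."),
    tpl("clinical", NA, "none",
        "Telephone encounter: medication refill requested and approved."),
    tpl("clinical", NA, "none",
        "Routine visit. Vital signs within normal limits. Continue current plan."),
    tpl("clinical", NA, "none",
        "Discussed diet and exercise counseling. Return to clinic in 6 months."),
    tpl("pathology", NA, "none",
        "SKIN, LEFT FOREARM, SHAVE: basal cell carcinoma, margins clear."),
    tpl("pathology", NA, "none",
        "COLON, SIGMOID, POLYP: tubular adenoma, negative for high-grade dysplasia."),
    tpl("pathology", NA, "none",
        "GALLBLADDER, CHOLECYSTECTOMY: chronic cholecystitis with cholelithiasis.")
  )
}

# valid (P, S) pairs with sampling weights; biopsy scores skew lower than
# surgery scores (upgrading is handled conditionally at draw time)
.GS_PAIRS <- data.frame(
  P = c(3L, 3L, 4L, 4L, 3L, 5L, 4L, 5L, 5L),
  S = c(3L, 4L, 3L, 4L, 5L, 3L, 5L, 4L, 5L),
  biopsy_w = c(0.28, 0.26, 0.16, 0.12, 0.02, 0.02, 0.06, 0.05, 0.03)
)

.render_template <- function(tpl, triple = NULL, mo = NULL, yr = NULL) {
  text <- tpl$text
  if (!is.null(triple)) {
    text <- gsub("{P}", triple$primary, text, fixed = TRUE)
    text <- gsub("{S}", triple$secondary, text, fixed = TRUE)
    text <- gsub("{T}", triple$total, text, fixed = TRUE)
  }
  if (!is.null(mo)) text <- gsub("{MO}", mo, text, fixed = TRUE)
  if (!is.null(yr)) text <- gsub("{YR}", yr, text, fixed = TRUE)
  text
}

# per-patient substream seed, counter-derived so that editing one patient's
# draws never cascades into another's
.patient_seed <- function(master, i) {
  base <- as.numeric(master) %% 2147483647
  as.integer((base * 69069 + i * 104729) %% 2147483647)
}

# deterministic replacement triple for cross-note conflicts; the first
# canonical valid triple that differs from `triple`
.conflict_triple <- function(triple) {
  cand <- list(c(4L, 3L), c(3L, 4L), c(4L, 4L), c(3L, 3L), c(4L, 5L),
               c(5L, 4L), c(3L, 5L), c(5L, 3L), c(5L, 5L))
  for (ps in cand) {
    tr <- gleason_triple(ps[1], ps[2], ps[1] + ps[2])
    if (!triple_equal(tr, triple)) return(tr)
  }
  stop("unreachable")  # nocov
}

#' Inject a complication into a rendered note
#'
#' Corrupts one score-bearing note (and its gold label) with one of the
#' three complication kinds the triage algorithm must catch:
#' * `inaccurate_sum` -- the explicitly written total is perturbed by one
#'   (upward, or downward at total 10) so the note literally reads e.g.
#'   "Gleason 3+4=8";
#' * `missing_component` -- the score expression is replaced by a
#'   primary-only statement ("Primary Gleason was 4") with no recoverable
#'   component pair left in the note;
#' * `cross_note_conflict` -- a second clinical note for the same task is
#'   fabricated carrying a different valid score (4+4=8 in pathology vs
#'   4+3=7 in clinic).
#'
#' @param note Single-row note data.frame (must contain an explicit score
#'   for `inaccurate_sum`).
#' @param gold Single-row gold label (list or data.frame row) with `P`,
#'   `S`, `T`, `corruption`, `expected_triage`.
#' @param kind One of the three corruption kinds.
#' @param lexicon Lexicon used to locate the score mention being rewritten.
#' @return list with `notes` (one- or two-row data.frame) and the updated
#'   `gold` row (`corruption = kind`, `expected_triage = "complicated"`).
#' @export
inject_complication <- function(note, gold,
                                kind = c("inaccurate_sum",
                                         "missing_component",
                                         "cross_note_conflict"),
                                lexicon = default_lexicon()) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(note), nrow(note) == 1L)
  text <- as.character(note$text)
  gold <- as.list(gold)

  if (kind == "inaccurate_sum") {
    m <- regexpr(.G_NUM_A, text, perl = TRUE)
    if (m[1] != -1L) total_grp <- 3L
    else {
      m <- regexpr(.G_NUM_C, text, perl = TRUE)
      total_grp <- 1L
    }
    if (m[1] == -1L)
      stop("note contains no explicitly written total to perturb",
           call. = FALSE)
    cs <- attr(m, "capture.start")[total_grp]
    cl <- attr(m, "capture.length")[total_grp]
    t_read <- as.integer(substr(text, cs, cs + cl - 1L))
    t_new <- if (t_read < 10L) t_read + 1L else t_read - 1L
    note$text <- paste0(substr(text, 1L, cs - 1L), t_new,
                        substr(text, cs + cl, nchar(text)))
    notes <- note
  } else if (kind == "missing_component") {
    anchors <- find_mentions(text, lexicon)
    if (!nrow(anchors))
      stop("note contains no Gleason mention to corrupt", call. = FALSE)
    parsed <- parse_components(text, c(anchors$start[1], anchors$end[1]),
                               .windows_from_lexicon(lexicon))
    cut_end <- max(anchors$end[1],
                   if (is.null(parsed$evidence_span)) 0L
                   else parsed$evidence_span[2])
    note$text <- paste0(substr(text, 1L, anchors$start[1] - 1L),
                        sprintf("Primary Gleason was %d", gold$P),
                        substr(text, cut_end + 1L, nchar(text)))
    notes <- note
  } else {  # cross_note_conflict
    other <- .conflict_triple(gleason_triple(gold$P, gold$S, gold$T))
    cue_sentence <- if (gold$specimen_type == "surgery")
      "Outside records reviewed: s/p radical prostatectomy with Gleason score %d+%d=%d."
    else
      "Per referral documentation, prostate needle biopsy demonstrated Gleason score %d+%d=%d."
    extra <- note
    extra$note_id <- paste0(note$note_id, "X")
    extra$note_type <- "clinical"
    extra$text <- sprintf(cue_sentence, other$primary, other$secondary,
                          other$total)
    notes <- rbind(note, extra)
  }
  gold$corruption <- kind
  gold$expected_triage <- "complicated"
  list(notes = notes, gold = gold)
}

#' Generate a synthetic note corpus with gold labels
#'
#' Emulates the kind of EHR corpus the extractor targets: each patient has
#' a documented biopsy score (surgery score with probability
#' `surgery_prob`, never lower in total than the biopsy -- pathologic
#' upgrading), rendered into pathology reports and clinical notes drawn
#' from the template bank across surface grammars (a)-(d), padded with
#' score-free filler notes to the configured per-patient note counts.
#' Corruptions are sampled per (patient, specimen) *task* at
#' `complication_rate` -- across all `2 * n_patients` tasks, so the
#' complicated-task count is Binomial(2n, rate) -- and injected via
#' [inject_complication()]; a corrupted task renders exactly one
#' score-bearing note (plus the fabricated conflicting note for
#' `cross_note_conflict`). A corrupted surgery task that would otherwise
#' have been undocumented gets a score instantiated, since every corruption
#' kind corrupts score text.
#'
#' Fully reproducible: the master seed drives counter-derived per-patient
#' substreams, so identical parameters give byte-identical corpora.
#'
#' @param params A [generator_params()] object.
#' @return list with `notes` (corpus data.frame, see [read_corpus()]) and
#'   `gold` (one row per task: `patient_id`, `specimen_type`, `P`, `S`,
#'   `T` -- `NA` for not-found -- `corruption`, `expected_triage`).
#' @examples
#' sim <- generate_corpus(generator_params(n_patients = 3, seed = 42))
#' nrow(sim$gold)  # 6 tasks: 2 per patient
#' @export
generate_corpus <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  bank <- params$template_bank
  pick <- function(note_type, specimen, grammars) {
    hits <- Filter(function(t) t$note_type == note_type &&
                     !is.na(t$specimen) && t$specimen == specimen &&
                     t$grammar %in% grammars, bank)
    if (!length(hits))
      stop("template bank has no ", note_type, "/", specimen,
           " template for grammar(s) ", paste(grammars, collapse = ","),
           call. = FALSE)
    hits[[sample.int(length(hits), 1L)]]
  }
  fillers <- function(note_type) {
    hits <- Filter(function(t) t$note_type == note_type &&
                     t$grammar == "none", bank)
    if (!length(hits))
      stop("template bank has no ", note_type, " filler template",
           call. = FALSE)
    hits
  }
  kinds <- names(params$kind_split)

  note_rows <- list()
  gold_rows <- list()
  for (i in seq_len(params$n_patients)) {
    set.seed(.patient_seed(params$seed, i))
    pid <- sprintf("P%05d", i)
    note_counter <- 0L
    new_note <- function(note_type, text) {
      note_counter <<- note_counter + 1L
      data.frame(patient_id = pid,
                 note_id = sprintf("%s-N%02d", pid, note_counter),
                 note_type = note_type,
                 note_date = sprintf("%d-%02d-%02d",
                                     sample(2005:2019, 1L),
                                     sample(1:12, 1L),
                                     sample(1:28, 1L)),
                 text = text, stringsAsFactors = FALSE)
    }

    # true scores
    bi <- sample.int(nrow(.GS_PAIRS), 1L, prob = .GS_PAIRS$biopsy_w)
    biopsy <- gleason_triple(.GS_PAIRS$P[bi], .GS_PAIRS$S[bi],
                             .GS_PAIRS$P[bi] + .GS_PAIRS$S[bi])
    surgery_doc <- stats::runif(1) < params$surgery_prob
    corrupt <- stats::runif(2) < params$complication_rate  # surgery, biopsy
    if (corrupt[1]) surgery_doc <- TRUE
    surgery <- NULL
    if (surgery_doc) {
      upgrade <- stats::runif(1) < params$upgrade_prob
      if (upgrade && biopsy$total < 10L) {
        higher <- which(.GS_PAIRS$P + .GS_PAIRS$S > biopsy$total)
        si <- higher[sample.int(length(higher), 1L,
                                prob = .GS_PAIRS$biopsy_w[higher])]
        surgery <- gleason_triple(.GS_PAIRS$P[si], .GS_PAIRS$S[si],
                                  .GS_PAIRS$P[si] + .GS_PAIRS$S[si])
      } else surgery <- biopsy
    }

    n_path <- 0L; n_clin <- 0L
    for (sp in c("surgery", "biopsy")) {
      truth <- if (sp == "surgery") surgery else biopsy
      is_corrupt <- corrupt[if (sp == "surgery") 1L else 2L]
      gold <- list(patient_id = pid, specimen_type = sp,
                   P = if (is.null(truth)) NA_integer_ else truth$primary,
                   S = if (is.null(truth)) NA_integer_ else truth$secondary,
                   T = if (is.null(truth)) NA_integer_ else truth$total,
                   corruption = "none", expected_triage = "uncomplicated")
      if (!is.null(truth)) {
        mo <- sample(1:12, 1L); yr <- sample(2005:2019, 1L)
        if (is_corrupt) {
          kind <- sample(kinds, 1L, prob = params$kind_split)
          tplp <- pick("pathology", sp, "a")  # explicit total, perturbable
          note <- new_note("pathology", .render_template(tplp, truth, mo, yr))
          inj <- inject_complication(note, gold, kind)
          for (j in seq_len(nrow(inj$notes))) {
            note_rows[[length(note_rows) + 1L]] <-
              inj$notes[j, , drop = FALSE]
            if (inj$notes$note_type[j] == "pathology") n_path <- n_path + 1L
            else n_clin <- n_clin + 1L
          }
          gold <- inj$gold
        } else {
          tplp <- pick("pathology", sp, c("a", "c"))
          note_rows[[length(note_rows) + 1L]] <-
            new_note("pathology", .render_template(tplp, truth, mo, yr))
          n_path <- n_path + 1L
          if (stats::runif(1) < params$echo_prob) {
            tplc <- pick("clinical", sp, c("a", "b", "c", "d"))
            note_rows[[length(note_rows) + 1L]] <-
              new_note("clinical", .render_template(tplc, truth,
                                                    sample(1:12, 1L),
                                                    sample(2005:2019, 1L)))
            n_clin <- n_clin + 1L
          }
        }
      }
      gold_rows[[length(gold_rows) + 1L]] <-
        as.data.frame(gold, stringsAsFactors = FALSE)
    }

    # pad with score-free filler to the configured per-patient note counts
    pf <- fillers("pathology"); cf <- fillers("clinical")
    target_path <- stats::rpois(1, params$notes_per_patient[["pathology"]])
    target_clin <- stats::rpois(1, params$notes_per_patient[["clinical"]])
    while (n_path < target_path) {
      note_rows[[length(note_rows) + 1L]] <-
        new_note("pathology", pf[[sample.int(length(pf), 1L)]]$text)
      n_path <- n_path + 1L
    }
    while (n_clin < target_clin) {
      note_rows[[length(note_rows) + 1L]] <-
        new_note("clinical", cf[[sample.int(length(cf), 1L)]]$text)
      n_clin <- n_clin + 1L
    }
  }

  notes <- do.call(rbind, note_rows)
  rownames(notes) <- NULL
  gold <- do.call(rbind, gold_rows)
  rownames(gold) <- NULL
  list(notes = validate_corpus(notes), gold = gold)
}
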