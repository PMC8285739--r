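#' Accuracy as a printed percentage
#'
#' `100 * (total - errors) / total`, rounded half-away-from-zero to one
#' decimal (so 95.25 prints as 95.3) -- the convention used throughout the
#' reporting here.
#'
#' @param errors,total Non-negative counts, `errors <= total`, `total > 0`.
#' @return Numeric percentage with one decimal.
#' @examples
#' accuracy_percent(5, 381)  # 98.7
#' @export
accuracy_percent <- function(errors, total) {
  stopifnot(length(errors) == 1L, length(total) == 1L)
  if (is.na(errors) || is.na(total) || total <= 0 || errors < 0 ||
      errors > total)
    stop("need 0 <= errors <= total and total > 0", call. = FALSE)
  x <- 100 * (total - errors) / total
  floor(x * 10 + 0.5 + 1e-9) / 10  # half away from zero (x >= 0)
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Computes the exact two-sided p-value for a 2x2 table by enumerating
#' every table compatible with the fixed margins and summing the
#' hypergeometric point probabilities of all tables at most as probable as
#' the observed one. "At most as probable" is assessed with a 1e-7
#' relative tolerance as a floating-point guard. Invariant under swapping
#' rows and under swapping columns.
#'
#' @param table 2x2 matrix (or table) of non-negative integer counts with
#'   at least one positive margin.
#' @return p-value in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(matrix(c(0, 5, 5, 0), 2))  # 2/252
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("'table' must be 2x2", call. = FALSE)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (r1 + r2 == 0)
    stop("at least one margin must be positive", call. = FALSE)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p0 <- stats::dhyper(m[1, 1], r1, r2, c1)
  sel <- probs <= p0 * (1 + 1e-7)
  if (all(sel)) return(1)  # the whole support is as extreme: p is exactly 1
  min(1, sum(probs[sel]))
}

# long (one row per task) view of the patient-level records table
.records_to_tasks <- function(predicted) {
  if (inherits(predicted, "gleason_extraction")) predicted <- predicted$records
  stopifnot(is.data.frame(predicted))
  rows <- lapply(c("surgery", "biopsy"), function(sp) {
    data.frame(patient_id = predicted$patient_id,
               specimen_type = sp,
               P = predicted[[paste0(sp, "_P")]],
               S = predicted[[paste0(sp, "_S")]],
               T = predicted[[paste0(sp, "_T")]],
               status = predicted[[paste0(sp, "_status")]],
               triage = predicted[[paste0(sp, "_triage")]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$specimen_type), , drop = FALSE]
}

#' Score extraction output against gold labels
#'
#' Joins predicted patient records with gold task labels and marks each
#' task's automated (pre-review) result correct or not: correct means the
#' full triple equals the gold triple component-by-component (4+3=7 vs
#' 3+4=7 is an error), or both sides are not-found. Human correctness is
#' either supplied (real review results) or simulated with a Bernoulli
#' error model per triage stratum -- defaulting to the observed review
#' error rates of 10/381 on uncomplicated and 0 on complicated tasks; the
#' simulation is a labelled stand-in for real annotators, not a claim
#' about them.
#'
#' @param predicted A `gleason_extraction` object or its `records`
#'   data.frame.
#' @param gold Gold data.frame (from [generate_corpus()] or
#'   [read_gold()]).
#' @param human_correct Optional logical vector (aligned to the row order
#'   of the returned outcomes: by patient then specimen) of real human
#'   results; when `NULL` they are simulated.
#' @param human_error_rates Named Bernoulli error probabilities
#'   `c(uncomplicated = , complicated = )` for the simulation.
#' @param seed Optional seed for the simulated human.
#' @return data.frame of class `task_outcomes`: `patient_id`,
#'   `specimen_type`, `triage`, `nlp_correct`, `human_correct`.
#' @export
score_tasks <- function(predicted, gold, human_correct = NULL,
                        human_error_rates = c(uncomplicated = 10 / 381,
                                              complicated = 0),
                        seed = NULL) {
  pred <- .records_to_tasks(predicted)
  stopifnot(is.data.frame(gold),
            all(c("patient_id", "specimen_type", "P", "S", "T") %in%
                  names(gold)))
  key <- function(d) paste(d$patient_id, d$specimen_type)
  if (anyDuplicated(key(gold)))
    stop("gold has duplicate (patient, specimen) tasks", call. = FALSE)
  idx <- match(key(pred), key(gold))
  if (anyNA(idx) || nrow(pred) != nrow(gold))
    stop("predicted and gold tasks do not match one-to-one", call. = FALSE)
  g <- gold[idx, , drop = FALSE]

  gold_found <- !is.na(g$T)
  nlp_correct <- ifelse(
    gold_found,
    pred$status == "extracted" &
      !is.na(pred$P) & pred$P == g$P &
      !is.na(pred$S) & pred$S == g$S &
      !is.na(pred$T) & pred$T == g$T,
    pred$status == "not_found")

  if (is.null(human_correct)) {
    stopifnot(all(c("uncomplicated", "complicated") %in%
                    names(human_error_rates)))
    if (!is.null(seed)) set.seed(seed)
    rate <- unname(human_error_rates[pred$triage])
    human_correct <- stats::runif(nrow(pred)) >= rate
  } else {
    stopifnot(is.logical(human_correct),
              length(human_correct) == nrow(pred))
  }
  out <- data.frame(patient_id = pred$patient_id,
                    specimen_type = pred$specimen_type,
                    triage = pred$triage,
                    nlp_correct = as.logical(nlp_correct),
                    human_correct = human_correct,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("task_outcomes", class(out))
  out
}

#' Compare human-alone, NLP-alone and NLP-assisted strategies
#'
#' Reproduces the three-strategy accuracy arithmetic on a set of task
#' outcomes: human-alone counts human errors on every task; NLP-alone
#' counts NLP errors on every task; NLP-assisted follows the allocation
#' rule -- NLP on uncomplicated tasks, human on complicated tasks -- so its
#' errors are the NLP errors among uncomplicated plus the human errors
#' among complicated. The human workload fraction under assistance is the
#' complicated share of tasks.
#'
#' @param outcomes A `task_outcomes` data.frame (see [score_tasks()]).
#' @return Object of class `strategy_report`: `table` (strategy, errors,
#'   total, accuracy_percent), `stratum` (error/total counts per triage
#'   stratum and extractor), `workload_fraction_human`; p-value slots are
#'   filled by [compare_report()].
#' @export
strategy_accuracies <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0,
            all(c("triage", "nlp_correct", "human_correct") %in%
                  names(outcomes)))
  n <- nrow(outcomes)
  comp <- outcomes$triage == "complicated"
  e_nlp_unc <- sum(!outcomes$nlp_correct & !comp)
  e_nlp_comp <- sum(!outcomes$nlp_correct & comp)
  e_hum_unc <- sum(!outcomes$human_correct & !comp)
  e_hum_comp <- sum(!outcomes$human_correct & comp)
  errors <- c(human_alone = e_hum_unc + e_hum_comp,
              nlp_alone = e_nlp_unc + e_nlp_comp,
              nlp_assisted = e_nlp_unc + e_hum_comp)
  structure(list(
    table = data.frame(
      strategy = names(errors),
      errors = as.integer(errors),
      total = n,
      accuracy_percent = vapply(errors, accuracy_percent, numeric(1),
                                total = n),
      stringsAsFactors = FALSE, row.names = NULL),
    stratum = list(n_uncomplicated = sum(!comp), n_complicated = sum(comp),
                   nlp_errors = c(uncomplicated = e_nlp_unc,
                                  complicated = e_nlp_comp),
                   human_errors = c(uncomplicated = e_hum_unc,
                                    complicated = e_hum_comp)),
    workload_fraction_human = sum(comp) / n,
    pvalues = NULL), class = "strategy_report")
}

#' Attach pairwise Fisher comparisons to a strategy report
#'
#' Builds error/correct 2x2 tables and computes exact two-sided p-values
#' for: NLP-assisted vs human-alone, NLP-assisted vs NLP-alone, and human
#' vs NLP restricted to the complicated stratum (where the two disagree
#' most). `NA` when a stratum is empty.
#'
#' @param report A `strategy_report`.
#' @return The report with `$pvalues` filled (named numeric vector).
#' @export
compare_report <- function(report) {
  stopifnot(inherits(report, "strategy_report"))
  tab <- report$table
  e <- stats::setNames(tab$errors, tab$strategy)
  n <- tab$total[1]
  two_arm <- function(e1, n1, e2, n2)
    fisher_exact_two_sided(rbind(c(e1, n1 - e1), c(e2, n2 - e2)))
  st <- report$stratum
  report$pvalues <- c(
    assisted_vs_human = two_arm(e[["nlp_assisted"]], n,
                                e[["human_alone"]], n),
    assisted_vs_nlp = two_arm(e[["nlp_assisted"]], n, e[["nlp_alone"]], n),
    human_vs_nlp_complicated = if (st$n_complicated > 0)
      two_arm(st$human_errors[["complicated"]], st$n_complicated,
              st$nlp_errors[["complicated"]], st$n_complicated)
    else NA_real_)
  report
}

#' @export
print.strategy_report <- function(x, ...) {
  cat("Extraction strategy comparison (", x$table$total[1], " tasks, ",
      sprintf("%.1f%%", 100 * x$workload_fraction_human),
      " human workload under assistance)\n\n", sep = "")
  tab <- x$table
  tab$accuracy_percent <- sprintf("%.1f", tab$accuracy_percent)
  print(tab, row.names = FALSE)
  if (!is.null(x$pvalues)) {
    cat("\nPairwise Fisher exact p-values:\n")
    print(signif(x$pvalues, 3))
  }
  invisible(x)
}

#' Evaluate a results file against a gold file
#'
#' File-level wrapper: reads the structured results CSV and the gold CSV,
#' scores tasks, compares strategies and writes a JSON report.
#'
#' @param pred Results CSV path (from [write_results()]).
#' @param gold Gold CSV path (from [write_gold()]).
#' @param report Optional JSON output path.
#' @param seed Seed for the simulated human extractor.
#' @return The annotated `strategy_report`, invisibly.
#' @export
run_evaluate <- function(pred, gold, report = NULL, seed = 1L) {
  records <- utils::read.csv(pred, stringsAsFactors = FALSE)
  g <- read_gold(gold)
  outcomes <- score_tasks(records, g, seed = seed)
  rep <- compare_report(strategy_accuracies(outcomes))
  if (!is.null(report)) {
    jsonlite::write_json(
      list(strategies = rep$table,
           workload_fraction_human = rep$workload_fraction_human,
           stratum = rep$stratum,
           pvalues = as.list(rep$pvalues)),
      report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(rep)
}
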