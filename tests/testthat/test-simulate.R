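test_that("composition-to-pattern assignment follows prevalence with grade tie-breaks", {
  expect_identical(
    assign_patterns_from_composition(c("3" = 0.15, "4" = 0.55, "5" = 0.30)),
    c(P = 4L, S = 5L))
  expect_identical(assign_patterns_from_composition(c("3" = 1.0)),
                   c(P = 3L, S = 3L))
  # exact tie: higher grade takes the contested slot
  expect_identical(assign_patterns_from_composition(c("3" = 0.5, "4" = 0.5)),
                   c(P = 4L, S = 3L))
  expect_error(assign_patterns_from_composition(c("2" = 0.5, "4" = 0.5)),
               "grades")
  expect_error(assign_patterns_from_composition(c("3" = 0.4, "4" = 0.4)),
               "sum to 1")
  expect_error(assign_patterns_from_composition(c(0.5, 0.5)), "named")
})

test_that("pattern assignment matches the argmax oracle over a 5% composition grid", {
  grid <- seq(0.05, 0.9, by = 0.05)
  for (f3 in grid) for (f4 in grid) {
    f5 <- round(1 - f3 - f4, 10)
    if (f5 < 0.05 - 1e-9) next
    comp <- c("3" = f3, "4" = f4, "5" = f5)
    expect_identical(assign_patterns_from_composition(comp),
                     oracle_patterns(comp),
                     info = paste(f3, f4, f5))
  }
  # two-grade compositions on the same grid
  for (f in grid) {
    comp <- c("3" = f, "5" = round(1 - f, 10))
    expect_identical(assign_patterns_from_composition(comp),
                     oracle_patterns(comp))
  }
})

test_that("generator parameters are validated and the seed is mandatory", {
  expect_error(generator_params(n_patients = 5), "seed")
  expect_error(generator_params(0, seed = 1), "n_patients")
  expect_error(generator_params(5, seed = 1, complication_rate = 1.5),
               "\\[0, 1\\]")
  expect_error(generator_params(5, seed = 1,
                                kind_split = c(inaccurate_sum = 1)),
               "kind_split")
  expect_error(generator_params(5, seed = 1, template_bank = list()),
               "empty template bank")
  p <- generator_params(5, seed = 1)
  expect_s3_class(p, "generator_params")
  expect_equal(sum(p$kind_split), 1)
})

test_that("identical parameters give byte-identical corpora; seeds differentiate", {
  p <- generator_params(8, seed = 33)
  s1 <- generate_corpus(p)
  s2 <- generate_corpus(p)
  expect_identical(s1, s2)
  s3 <- generate_corpus(generator_params(8, seed = 34))
  expect_false(identical(s1$notes$text, s3$notes$text))
})

test_that("gold structure: two tasks per patient, corruptions imply complicated", {
  sim <- generate_corpus(generator_params(25, seed = 5,
                                          complication_rate = 0.2))
  expect_identical(nrow(sim$gold), 50L)
  expect_identical(sort(unique(sim$gold$specimen_type)),
                   c("biopsy", "surgery"))
  corrupted <- sim$gold$corruption != "none"
  expect_true(all(sim$gold$expected_triage[corrupted] == "complicated"))
  expect_true(all(sim$gold$expected_triage[!corrupted] == "uncomplicated"))
  # documented true triples are valid scores
  doc <- !is.na(sim$gold$T)
  expect_true(all(sim$gold$P[doc] + sim$gold$S[doc] == sim$gold$T[doc]))
  expect_true(all(sim$gold$P[doc] %in% 3:5 & sim$gold$S[doc] %in% 3:5))
  # biopsy truth is always documented; surgery upgrading never downgrades
  expect_true(all(!is.na(sim$gold$T[sim$gold$specimen_type == "biopsy"])))
  g <- sim$gold
  for (pid in unique(g$patient_id)) {
    ts <- g$T[g$patient_id == pid & g$specimen_type == "surgery"]
    tb <- g$T[g$patient_id == pid & g$specimen_type == "biopsy"]
    if (!is.na(ts)) expect_gte(ts, tb)
  }
})

test_that("every rendered score is anchored: notes admit extraction wherever gold has truth", {
  sim <- generate_corpus(generator_params(12, seed = 21,
                                          complication_rate = 0))
  res <- extract_gleason(sim$notes)
  doc <- sim$gold[!is.na(sim$gold$T), ]
  for (i in seq_len(nrow(doc))) {
    rec <- res$records[res$records$patient_id == doc$patient_id[i], ]
    expect_identical(rec[[paste0(doc$specimen_type[i], "_status")]],
                     "extracted")
  }
})

test_that("clean corpora round-trip with 100% task accuracy", {
  for (seed in c(2, 17)) {
    sim <- generate_corpus(generator_params(30, seed = seed,
                                            complication_rate = 0))
    res <- extract_gleason(sim$notes)
    expect_length(res$queue, 0L)
    out <- score_tasks(res, sim$gold,
                       human_correct = rep(TRUE, nrow(sim$gold)))
    expect_true(all(out$nlp_correct))
  }
})

test_that("corruption injection rewrites notes exactly as specified", {
  note <- data.frame(patient_id = "p", note_id = "n1",
                     note_type = "pathology", note_date = "2016-01-01",
                     text = "Needle biopsy: Gleason score 3+4=7, left base.",
                     stringsAsFactors = FALSE)
  gold <- list(patient_id = "p", specimen_type = "biopsy", P = 3L, S = 4L,
               T = 7L, corruption = "none",
               expected_triage = "uncomplicated")
  inj <- inject_complication(note, gold, "inaccurate_sum")
  expect_match(inj$notes$text, "3+4=8", fixed = TRUE)
  expect_identical(inj$gold$expected_triage, "complicated")

  inj2 <- inject_complication(note, gold, "missing_component")
  expect_match(inj2$notes$text, "Primary Gleason was 3", fixed = TRUE)
  expect_false(grepl("3+4", inj2$notes$text, fixed = TRUE))

  gold_s <- list(patient_id = "p", specimen_type = "surgery", P = 4L,
                 S = 4L, T = 8L, corruption = "none",
                 expected_triage = "uncomplicated")
  note_s <- note
  note_s$text <- "Radical prostatectomy: Gleason score 4+4=8."
  inj3 <- inject_complication(note_s, gold_s, "cross_note_conflict")
  expect_identical(nrow(inj3$notes), 2L)
  expect_identical(inj3$notes$note_type[2], "clinical")
  expect_match(inj3$notes$text[2], "4+3=7", fixed = TRUE)  # conflicting score
  # a note with no explicit total cannot take an inaccurate-sum corruption
  note_b <- note
  note_b$text <- "PNBx: Gleason 4+3."
  expect_error(inject_complication(note_b, gold, "inaccurate_sum"), "total")
})

test_that("pipelined corruptions are always flagged with the matching reason", {
  sim <- generate_corpus(generator_params(40, seed = 13,
                                          complication_rate = 0.3))
  res <- extract_gleason(sim$notes)
  key <- vapply(res$tasks, function(t)
    paste(t$patient_id, t$specimen_type), "")
  reason_of <- c(inaccurate_sum = "inaccurate",
                 missing_component = "incomplete",
                 cross_note_conflict = "conflicting")
  for (i in seq_len(nrow(sim$gold))) {
    task <- res$tasks[[match(paste(sim$gold$patient_id[i],
                                   sim$gold$specimen_type[i]), key)]]
    if (sim$gold$corruption[i] != "none") {
      expect_identical(task$triage, "complicated")
      expect_true(reason_of[[sim$gold$corruption[i]]] %in% task$reasons)
    } else {
      expect_identical(task$triage, "uncomplicated")
    }
  }
})

test_that("flagged-task counts track the configured complication rate binomially", {
  # generation-level check across seeds: complicated gold tasks out of 2n
  # should stay within 3 binomial standard deviations of 2n * rate
  n <- 100L; rate <- 0.05
  for (seed in 101:106) {
    sim <- generate_corpus(generator_params(n, seed = seed,
                                            complication_rate = rate))
    flagged <- sum(sim$gold$expected_triage == "complicated")
    expect_lt(abs(flagged - 2 * n * rate),
              3 * sqrt(2 * n * rate * (1 - rate)) + 1e-9)
  }
})
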