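test_that("task construction yields two tasks per patient and routes by specimen", {
  m <- list(mk_mention("p1", "n1", 3, 4, 7, specimen = "biopsy"))
  tasks <- build_tasks(m)
  expect_length(tasks, 2L)
  expect_length(task_for(tasks, "p1", "biopsy")$mentions, 1L)
  expect_length(task_for(tasks, "p1", "surgery")$mentions, 0L)

  tasks6 <- build_tasks(list(), patients = c("a", "b", "c"))
  expect_length(tasks6, 6L)
  expect_true(all(vapply(tasks6, function(t) length(t$mentions), 0L) == 0L))

  # an unclassified mention attaches to both of the patient's tasks
  mu <- list(mk_mention("p1", "n1", 3, 4, 7, specimen = "unclassified"))
  tu <- build_tasks(mu)
  expect_true(all(vapply(tu, function(t) length(t$mentions), 0L) == 1L))
  expect_true(tu[[1]]$mentions[[1]]$attached)

  bad <- mk_mention("p1", "n1", 3, 4, 7)
  bad$patient_id <- NA_character_
  expect_error(build_tasks(list(bad)), "patient_id")
})

test_that("cross-note conflict detection follows the different-notes different-triples rule", {
  t_of <- function(mentions) {
    structure(list(patient_id = "p", specimen_type = "surgery",
                   mentions = mentions, triage = NA_character_,
                   reasons = character()), class = "gleason_task")
  }
  path <- mk_mention("p", "path1", 4, 4, 8, specimen = "surgery")
  clin <- mk_mention("p", "clin1", 4, 3, 7, specimen = "surgery")
  expect_true(detect_conflicts(t_of(list(path, clin))))
  # agreement across notes
  clin_same <- mk_mention("p", "clin1", 4, 4, 8, specimen = "surgery")
  expect_false(detect_conflicts(t_of(list(path, clin_same))))
  # a single note never conflicts with itself
  same_note <- mk_mention("p", "path1", 4, 3, 7, specimen = "surgery")
  expect_false(detect_conflicts(t_of(list(path, same_note))))
  expect_false(detect_conflicts(t_of(list(path))))
  # invalid mentions never participate
  inac <- mk_mention("p", "clin2", 3, 4, 8, specimen = "surgery")
  expect_false(detect_conflicts(t_of(list(path, inac))))
  # triples mode flags reordered components; totals mode does not
  reord <- mk_mention("p", "clin3", 3, 4, 7, specimen = "surgery")
  clin2 <- mk_mention("p", "clin4", 4, 3, 7, specimen = "surgery")
  expect_true(detect_conflicts(t_of(list(reord, clin2)), mode = "triples"))
  expect_false(detect_conflicts(t_of(list(reord, clin2)), mode = "totals"))
})

test_that("triage reproduces the three complication exemplars and the escalation rules", {
  # inaccurate: the note literally says 3+4=8
  t1 <- mk_tasks(list(mk_mention("p", "n1", 3, 4, 8, specimen = "biopsy")))
  task <- task_for(t1, "p", "biopsy")
  expect_identical(task$triage, "complicated")
  expect_identical(task$reasons, "inaccurate")

  # incomplete: only a primary pattern anywhere for the task
  t2 <- mk_tasks(list(mk_mention("p", "n1", P = 4, specimen = "biopsy")))
  task <- task_for(t2, "p", "biopsy")
  expect_identical(task$reasons, "incomplete")

  # incomplete is downgraded when a valid mention supplies the task
  t3 <- mk_tasks(list(mk_mention("p", "n1", T = 7, specimen = "biopsy"),
                      mk_mention("p", "n2", 3, 4, 7, specimen = "biopsy")))
  task <- task_for(t3, "p", "biopsy")
  expect_identical(task$triage, "uncomplicated")

  # conflicting: surgery pathology 4+4=8 vs clinical 4+3=7
  m_path <- mk_mention("p", "path1", 4, 4, 8, specimen = "surgery")
  m_path$note_type <- "pathology"
  t4 <- mk_tasks(list(m_path,
                      mk_mention("p", "clin1", 4, 3, 7, specimen = "surgery")))
  task <- task_for(t4, "p", "surgery")
  expect_identical(task$reasons, "conflicting")

  # unclassified valid evidence with no classified backup escalates both tasks
  t5 <- mk_tasks(list(mk_mention("p", "n1", 3, 4, 7,
                                 specimen = "unclassified")))
  expect_true(all(vapply(t5, function(t) t$triage, "") == "complicated"))
  expect_true(all(vapply(t5, function(t)
    "unclassified_specimen" %in% t$reasons, NA)))
  # ... but not when the task has its own classified valid mention
  t6 <- mk_tasks(list(
    mk_mention("p", "n1", 3, 4, 7, specimen = "unclassified"),
    mk_mention("p", "n2", 3, 4, 7, specimen = "biopsy")))
  expect_identical(task_for(t6, "p", "biopsy")$triage, "uncomplicated")

  # empty task: uncomplicated, outcome not found
  t7 <- mk_tasks(list(), patients = "p")
  expect_identical(task_for(t7, "p", "surgery")$triage, "uncomplicated")
  expect_identical(aggregate_task(task_for(t7, "p", "surgery")), "not_found")
})

test_that("aggregation takes the maximum score with the documented tie-breaks", {
  mk_t <- function(...) {
    tasks <- mk_tasks(list(...))
    task_for(tasks, "p", "biopsy")
  }
  # max by total
  t <- mk_t(mk_mention("p", "n1", 3, 3, 6, specimen = "biopsy"),
            mk_mention("p", "n1", 4, 5, 9, specimen = "biopsy"))
  expect_true(triple_equal(aggregate_task(t), gleason_triple(4, 5, 9)))
  # tie on total: higher primary wins (4+3 over 3+4)
  t <- mk_t(mk_mention("p", "n1", 3, 4, 7, specimen = "biopsy"),
            mk_mention("p", "n1", 4, 3, 7, specimen = "biopsy"))
  expect_true(triple_equal(aggregate_task(t), gleason_triple(4, 3, 7)))
  # invalid mentions contribute nothing
  t <- mk_t(mk_mention("p", "n1", 3, 4, 8, specimen = "biopsy"))
  expect_identical(aggregate_task(t), "not_found")
})

test_that("aggregation is permutation-invariant and monotone in added evidence", {
  pairs <- list(c(3, 3), c(3, 4), c(4, 3), c(4, 4), c(3, 5), c(4, 5),
                c(5, 4), c(5, 5))
  set.seed(7)
  for (rep in 1:20) {
    chosen <- sample(pairs, sample(2:5, 1), replace = TRUE)
    mentions <- lapply(seq_along(chosen), function(i)
      mk_mention("p", paste0("n", i), chosen[[i]][1], chosen[[i]][2],
                 sum(chosen[[i]]), specimen = "biopsy"))
    base_task <- task_for(mk_tasks(mentions), "p", "biopsy")
    base <- aggregate_task(base_task)
    for (k in 1:4) {
      perm <- sample(mentions)
      t2 <- task_for(mk_tasks(perm), "p", "biopsy")
      expect_true(triple_equal(aggregate_task(t2), base))
    }
    # adding one more valid mention never lowers the total
    extra <- mk_mention("p", "nx", 3, 3, 6, specimen = "biopsy")
    t3 <- task_for(mk_tasks(c(mentions, list(extra))), "p", "biopsy")
    expect_gte(aggregate_task(t3)$total, base$total)
  }
})

test_that("cohort assembly conserves tasks and splits the review queue correctly", {
  mentions <- c(
    list(mk_mention("a", "a1", 3, 4, 7, specimen = "biopsy")),
    list(mk_mention("b", "b1", 3, 4, 8, specimen = "biopsy")),   # complicated
    list(mk_mention("c", "c1", 4, 4, 8, specimen = "surgery"),
         mk_mention("c", "c2", 4, 3, 7, specimen = "surgery")))  # conflict
  tasks <- mk_tasks(mentions, patients = c("a", "b", "c", "d"))
  out <- assemble_cohort(tasks)
  expect_identical(nrow(out$records), 4L)             # one row per patient
  expect_length(tasks, 8L)                            # 2 x patients
  n_comp <- sum(vapply(tasks, function(t) t$triage == "complicated", NA))
  expect_length(out$queue, n_comp)
  expect_identical(length(out$queue) +
                     sum(vapply(tasks, function(t)
                       t$triage == "uncomplicated", NA)),
                   length(tasks))
  # every emitted (non-draft) score on an uncomplicated task is a valid triple
  rec <- out$records
  a <- rec[rec$patient_id == "a", ]
  expect_identical(c(a$biopsy_P, a$biopsy_S, a$biopsy_T), c(3L, 4L, 7L))
  expect_identical(a$biopsy_status, "extracted")
  expect_identical(rec[rec$patient_id == "d", "surgery_status"], "not_found")
  # complicated task keeps its draft and reasons in the record
  cpx <- rec[rec$patient_id == "c", ]
  expect_identical(cpx$surgery_triage, "complicated")
  expect_identical(cpx$surgery_reasons, "conflicting")
  expect_identical(cpx$surgery_T, 8L)  # draft aggregate = max
  # queue entries carry evidence for the reviewer
  q <- out$queue[[1]]
  expect_true(all(c("patient_id", "specimen_type", "reasons", "draft",
                    "evidence") %in% names(q)))
  # unsorted/triaged guard
  raw <- build_tasks(mentions, patients = "a")
  expect_error(assemble_cohort(raw), "triaged")
})
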