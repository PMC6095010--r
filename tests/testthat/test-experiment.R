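# End-to-end solving, response classification, and the longitudinal
# protocol.

test_that("inhibition draws match the group distribution and clip range", {
  set.seed(50)
  g <- group_config("low")
  x <- sample_inhibition(g, 10000)
  expect_lt(abs(mean(x) - 0.4), 0.01)
  expect_lt(abs(sd(x) - 0.1), 0.01)
  expect_true(all(x >= 0.05 & x <= 1))
  set.seed(50)
  expect_identical(sample_inhibition(g, 10000), x)
})

test_that("group configurations implement the two knowledge schedules", {
  lo <- group_config("high")
  hk <- group_config("high_knowledge")
  expect_identical(lo$n_trials, 800L)
  expect_identical(hk$n_trials, 1000L)
  # schedule endpoints stay within the trained horizon
  expect_lte(100 * lo$n_phases + lo$checkpoint_offset, lo$n_trials)
  expect_lte(100 * hk$n_phases + hk$checkpoint_offset, hk$n_trials)
  expect_identical(hk$mu, 0.8)
})

test_that("answers are classified by the transformations correctly inferred", {
  set.seed(60)
  pb <- doralisa:::make_problem(c("unary", "unary"), "medium", 1000)
  c_obj <- c(101L, 102L)
  mk_ans <- function(pairs_list) {
    structure(list(inferred = lapply(pairs_list, function(pp) {
      list(pairs = pp)
    }), empty = length(pairs_list) == 0, c_objects = c_obj),
    class = "dora_answer")
  }
  t1 <- pb$correct_d[[1]]$pairs[[1]]$role
  t2 <- pb$correct_d[[2]]$pairs[[1]]$role
  full <- mk_ans(list(list(list(role = t1, obj = 101L)),
                      list(list(role = t2, obj = 102L))))
  expect_identical(as.character(classify_response(full, pb)$outcome),
                   "analogical")
  part <- mk_ans(list(list(list(role = t1, obj = 101L)),
                      list(list(role = t2, obj = 101L))))
  cl <- classify_response(part, pb)
  expect_identical(as.character(cl$outcome), "incomplete")
  expect_identical(cl$n_correct, 1L)
  # a bare copy of C's objects with no correct relational structure
  copy <- mk_ans(list(list(list(role = NA_character_, obj = 101L)),
                      list(list(role = NA_character_, obj = 102L))))
  expect_identical(as.character(classify_response(copy, pb)$outcome),
                   "associative")
  expect_identical(as.character(classify_response(mk_ans(list()), pb)$outcome),
                   "associative")
})

test_that("equivalent transformation instances are interchangeable in scoring", {
  set.seed(61)
  pb <- doralisa:::make_problem(c("binary", "binary"), "medium", 1000)
  c_obj <- 101:104
  # answer with the two containment instances exchanged wholesale
  pairs <- lapply(pb$correct_d[c(2, 1)], function(inst) {
    lapply(inst$pairs, function(pr) list(role = pr$role,
                                         obj = c_obj[pr$obj]))
  })
  ans <- structure(list(inferred = lapply(pairs, function(pp) {
    list(pairs = pp)
  }), empty = FALSE, c_objects = c_obj), class = "dora_answer")
  expect_identical(as.character(classify_response(ans, pb)$outcome),
                   "analogical")
})

test_that("clean representations solve an easy problem analogically", {
  fit <- fixture_learning(lambda = 0.9, n_trials = 400, seed = 2024)
  set.seed(70)
  hits <- 0
  for (i in 1:10) {
    pb <- doralisa:::make_problem("unary", "easy", 1000)
    ans <- solve_problem(pb, fit, 400, lambda = 0.9)
    hits <- hits + (classify_response(ans, pb)$outcome == "analogical")
  }
  expect_gte(hits, 8)
})

test_that("a transformation whose predicate was never learned cannot be inferred", {
  # the two-object world only ever teaches the doubling predicate
  set.seed(71)
  fit <- learn_relations(two_object_world("doubling"), lambda = 0.95,
                         n_trials = 100)
  for (i in 1:5) {
    pb <- doralisa:::make_problem(c("unary", "unary"), "medium", 100)
    types <- vapply(pb$instances, `[[`, character(1), "type")
    ans <- solve_problem(pb, fit, 100, lambda = 0.95)
    cl <- classify_response(ans, pb)
    expect_lte(cl$n_correct, sum(types == "doubling"))
    expect_true(cl$outcome != "analogical" || all(types == "doubling"))
  }
})

test_that("the protocol yields the full trial ledger, with lambda fixed per individual", {
  g <- group_config("low", n_sims = 2)
  g$n_phases <- 2L
  rec <- run_group(g, seed = 123)
  expect_identical(nrow(rec), 2L * 2L * 20L)
  expect_identical(sort(unique(rec$phase)), 1:2)
  for (s in unique(rec$sim)) {
    expect_length(unique(rec$lambda[rec$sim == s]), 1)
  }
  expect_identical(unique(rec$checkpoint[rec$phase == 2]), 200L)
  # reproducible under the same seed
  rec2 <- run_group(g, seed = 123)
  expect_identical(rec, rec2)
})

test_that("aggregation partitions every trial and sums to 100 per group", {
  g <- group_config("medium", n_sims = 2)
  g$n_phases <- 2L
  ex <- aggregate_results(run_group(g, seed = 5))
  expect_s3_class(ex, "dora_experiment")
  tot <- tapply(ex$summary_table$percent, ex$summary_table$group, sum)
  expect_true(all(abs(tot - 100) < 1e-9))
  ph <- tapply(ex$trajectories$percent,
               list(ex$trajectories$group, ex$trajectories$phase), sum)
  expect_true(all(abs(ph - 100) < 1e-9))
  expect_error(aggregate_results(ex$records[0, ]), "no trial records")
})

test_that("experiment CSV outputs are written and re-readable", {
  g <- group_config("high", n_sims = 1)
  g$n_phases <- 1L
  ex <- aggregate_results(run_group(g, seed = 77))
  dir <- withr::local_tempdir()
  paths <- write_experiment_csv(ex, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(back$percent, ex$summary_table$percent)
})
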