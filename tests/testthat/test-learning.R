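# Comparison-based predicate discovery, the quality metric, and the
# learning-phase properties.

test_that("shared semantics become twice as active as unshared ones", {
  act <- coactive_semantics(c("1" = 1, "2" = 1, "3" = 1),
                            c("2" = 1, "3" = 1, "4" = 1))
  expect_equal(act[c("2", "3")], c("2" = 1, "3" = 1))
  expect_equal(act[c("1", "4")], c("1" = 0.5, "4" = 0.5))
})

test_that("full and zero overlap are degenerate co-activation cases", {
  w <- c("1" = 1, "2" = 1)
  expect_true(all(coactive_semantics(w, w) == 1))
  act <- coactive_semantics(c("1" = 1, "2" = 1), c("3" = 1, "4" = 1))
  expect_true(all(act == 0.5))  # uniform: no structure to learn from
})

test_that("recruited predicates learn weights proportional to activation", {
  a <- c("5" = 1, "6" = 1, "1" = 1)
  b <- c("5" = 1, "6" = 1, "2" = 1)
  w1 <- predicate_from_comparison(a, b, gamma = 1)
  expect_equal(w1[c("5", "6")], c("5" = 1, "6" = 1))
  expect_equal(unname(w1[c("1", "2")]), c(0.5, 0.5))
  w2 <- predicate_from_comparison(a, b, gamma = 0.3)
  expect_equal(unname(w2[c("5", "6")]), c(0.3, 0.3))
  expect_equal(unname(w2[c("1", "2")]), c(0.15, 0.15))
})

test_that("comparing two role-sharing objects isolates the role semantics", {
  # both objects carry the inside semantics; the learned predicate's two
  # strongest connections are exactly the inside-defining semantics
  ins <- role_semantics()$inside
  a <- stats::setNames(rep(1, 6), as.character(c(ins, 20, 21, 22, 23)))
  b <- stats::setNames(rep(1, 6), as.character(c(ins, 30, 31, 32, 33)))
  w <- predicate_from_comparison(a, b, gamma = 1)
  top2 <- names(sort(w, decreasing = TRUE))[1:2]
  expect_setequal(top2, as.character(ins))
})

test_that("predicate recruitment in a network also recruits RBs", {
  net <- dora_network(pool_size = 100)
  ltm <- add_analog(net, "ltm")
  o1 <- create_object(net, c(6, 7, 20, 21), ltm)
  o2 <- create_object(net, c(6, 7, 30, 31), ltm)
  res <- predicate_from_comparison(get_token(net, o1), get_token(net, o2),
                                   gamma = 1, net = net, analog = ltm)
  expect_identical(get_token(net, res$pred)$kind, "predicate")
  expect_length(res$rb, 2)
  for (rb in res$rb) {
    expect_identical(get_token(net, rb)$meta$pred, res$pred)
  }
})

test_that("relation formation needs at least two co-firing RBs", {
  f <- contains_fixture()
  rbs <- as.integer(names(get_token(f$net, f$p_a)$down))
  expect_null(form_relation(f$net, rbs[1], f$recipient))
  p <- form_relation(f$net, rbs, f$recipient)
  expect_identical(get_token(f$net, p)$layer, "P")
  expect_setequal(get_token(f$net, p)$meta$rbs, rbs)
  # a ternary structure is permitted
  net <- f$net
  extra <- make_proposition(net, list(c(f$out_d, f$house)), f$driver)
  p3 <- form_relation(net, c(rbs, extra), f$driver)
  expect_length(get_token(net, p3)$meta$rbs, 3)
})

test_that("quality matches its closed form and stays in [0, 1]", {
  expect_equal(quality(c("1" = 0.9, "2" = 0.8, "3" = 0.2, "4" = 0.2),
                       c(1, 2)),
               0.85 / 1.2, tolerance = 1e-12)
  # perfect predicate: no other connections
  expect_equal(quality(c("1" = 1, "2" = 1), c(1, 2)), 1)
  # all relevant weights zero
  expect_equal(quality(c("3" = 0.4), c(1, 2)), 0)
  # object POs have no quality
  net <- dora_network(pool_size = 10)
  ltm <- add_analog(net, "ltm")
  o <- create_object(net, c(1, 2), ltm)
  expect_error(quality(get_token(net, o), c(1, 2)), "predicate")
  # bounded for every learned predicate
  fit <- fixture_learning(lambda = 0.4, n_trials = 200, seed = 3)
  expect_true(all(fit$quality_by_role >= 0 & fit$quality_by_role <= 1))
})

test_that("Hebbian accumulation over repeated comparisons follows min(1, k*gamma)", {
  gamma <- 0.15
  a <- c("6" = 1, "7" = 1, "20" = 1, "21" = 1)
  b <- c("6" = 1, "7" = 1, "30" = 1, "31" = 1)
  w <- predicate_from_comparison(a, b, gamma = gamma)
  for (k in 2:8) {
    w <- predicate_from_comparison(a, b, gamma = gamma, base = w)
    expect_equal(unname(w[c("6", "7")]), rep(min(1, k * gamma), 2),
                 tolerance = 1e-12)
  }
})

test_that("deterministic learning on a two-object fixture yields exact Hebbian multiples", {
  # lambda = 1: selection is argmax, and the only shared structure is the
  # doubling role, so every predicate's connection to it is an exact
  # accumulation step min(1, k * gamma)
  set.seed(6)
  cfg <- dora_config()
  fit <- learn_relations(two_object_world("doubling"), lambda = 1,
                         n_trials = 100, config = cfg)
  sems <- as.character(role_semantics()$doubling)
  for (p in fit$predicates) {
    w <- p$w[sems]
    w <- w[!is.na(w)]
    k <- w / cfg$gamma
    expect_true(all(abs(k - round(k)) < 1e-9 | abs(w - 1) < 1e-9))
  }
  # and the strongest predicate saturates
  expect_equal(max(vapply(fit$predicates,
                          function(p) max(p$w[sems], 0, na.rm = TRUE),
                          numeric(1))), 1)
})

test_that("learning trials must cover at least one checkpoint", {
  expect_error(learn_relations(two_object_world(), 0.8, n_trials = 50),
               "checkpoint")
})

test_that("checkpoints are emitted every 100 trials with bounded quality", {
  fit <- fixture_learning(lambda = 0.9, n_trials = 400, seed = 2024)
  expect_identical(fit$checkpoints$trial, seq(100L, 400L, by = 100L))
  expect_true(all(fit$checkpoints$mean_quality >= 0 &
                    fit$checkpoints$mean_quality <= 1))
  # learned predicates become available cumulatively
  expect_true(all(diff(fit$checkpoints$n_predicates) >= 0))
})

test_that("representation quality improves over unstructured training", {
  # monotone learning property over seeds at high inhibition
  q <- vapply(1:8, function(s) {
    set.seed(s)
    fit <- learn_relations(generate_world(), lambda = 0.8, n_trials = 300)
    fit$checkpoints$mean_quality[c(1, 3)]
  }, numeric(2))
  expect_gt(mean(q[2, ] - q[1, ]), 0)
  # improvement in nearly every run, and never a material decline
  expect_gte(sum(q[2, ] > q[1, ]), 7)
  expect_true(all(q[2, ] - q[1, ] > -0.02))
})
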