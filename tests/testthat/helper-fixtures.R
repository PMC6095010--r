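# Fixtures are built in code: small hand-coded analog pairs for the
# mapping machinery, and cached learning runs for end-to-end tests.

# Driver with contains(house, square) [+ optionally a B term], recipient
# with contains(circle, triangle); featurally disjoint fillers, role
# predicates defined by the containment semantics.
contains_fixture <- function(b_term = c("none", "swap", "copy", "shield"),
                             lambda = 0.9) {
  b_term <- match.arg(b_term)
  net <- dora_network(pool_size = 100, inhibition = lambda)
  d <- add_analog(net, "driver")
  r <- add_analog(net, "recipient")
  out_d <- create_predicate(net, c("8" = 1, "9" = 1), d,
                            meta = list(role = "outside"))
  in_d <- create_predicate(net, c("10" = 1, "11" = 1), d,
                           meta = list(role = "inside"))
  house <- create_object(net, c(20, 21, 22, 23), d)
  square <- create_object(net, c(24, 25, 26, 27), d)
  out_r <- create_predicate(net, c("8" = 1, "9" = 1), r,
                            meta = list(role = "outside"))
  in_r <- create_predicate(net, c("10" = 1, "11" = 1), r,
                           meta = list(role = "inside"))
  circle <- create_object(net, c(30, 31, 32, 33), r)
  triangle <- create_object(net, c(34, 35, 36, 37), r)
  p_a <- make_proposition(net, list(c(out_d, house), c(in_d, square)), d)
  p_c <- make_proposition(net, list(c(out_r, circle), c(in_r, triangle)), r)
  p_b <- switch(b_term,
    none = NA_integer_,
    swap = make_proposition(net, list(c(out_d, square), c(in_d, house)), d),
    copy = make_proposition(net, list(c(out_d, house), c(in_d, square)), d),
    shield = {
      shield <- create_object(net, c(40, 41, 42, 43), d)
      make_proposition(net, list(c(out_d, square), c(in_d, shield)), d)
    })
  list(net = net, driver = d, recipient = r,
       out_d = out_d, in_d = in_d, house = house, square = square,
       out_r = out_r, in_r = in_r, circle = circle, triangle = triangle,
       p_a = p_a, p_b = p_b, p_c = p_c)
}

# two-object world whose objects share exactly one transformation's
# semantics and nothing else (features disjoint)
two_object_world <- function(role = "doubling") {
  sems <- role_semantics()[[role]]
  mk <- function(feats) {
    w <- rep(1, 2 + length(feats))
    names(w) <- as.character(c(sems, feats))
    list(w = w, transforms = role, roles = role, features = feats)
  }
  structure(list(objects = list(mk(c(50, 51, 52, 53)),
                                mk(c(60, 61, 62, 63))),
                 n_objects = 2L, pool_size = 100L, n_features = 4L),
            class = "dora_world")
}

# cached learning runs so several tests can share one fit
.fits <- new.env(parent = emptyenv())
fixture_learning <- function(lambda = 0.9, n_trials = 400L, seed = 2024L) {
  key <- paste(lambda, n_trials, seed, sep = "_")
  if (is.null(.fits[[key]])) {
    set.seed(seed)
    world <- generate_world()
    .fits[[key]] <- learn_relations(world, lambda, n_trials)
  }
  .fits[[key]]
}

# cached desk-scale run of the full longitudinal protocol (shared by the
# acceptance tests for the pooled table and the trajectory orderings)
fixture_experiment <- function() {
  if (is.null(.fits[["experiment"]])) {
    .fits[["experiment"]] <- simulate_trajectories(n_sims = 30L,
                                                   seed = 20240101L)
  }
  .fits[["experiment"]]
}

pooled_pct <- function(ex, group, outcome) {
  st <- ex$summary_table
  st$percent[st$group == group & st$outcome == outcome]
}
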