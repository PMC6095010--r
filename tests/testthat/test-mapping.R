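# Analogical mapping between driver and recipient, and self-supervised
# inference of the missing term.

test_that("corresponding roles and fillers map under strong inhibition", {
  for (s in 1:5) {
    set.seed(s)
    f <- contains_fixture()
    mp <- map_analogs(f$net, f$driver, f$recipient, lambda = 0.9)
    w <- mp$winners$po
    expect_identical(unname(w[as.character(f$out_d)]), f$out_r)
    expect_identical(unname(w[as.character(f$in_d)]), f$in_r)
    # featurally disjoint fillers map through their shared roles
    expect_identical(unname(w[as.character(f$house)]), f$circle)
    expect_identical(unname(w[as.character(f$square)]), f$triangle)
  }
})

test_that("an analog maps onto a copy of itself identically at every layer", {
  set.seed(10)
  net <- dora_network(pool_size = 100, inhibition = 0.95)
  d <- add_analog(net, "driver"); r <- add_analog(net, "recipient")
  ids <- list()
  for (bank in list(d, r)) {
    pr <- create_predicate(net, c("6" = 1, "7" = 1), bank,
                           meta = list(role = "doubling"))
    ob <- create_object(net, c(40, 41, 42), bank)
    pp <- make_proposition(net, list(c(pr, ob)), bank)
    ids[[length(ids) + 1]] <- c(pr = pr, ob = ob, rb = pp)
  }
  mp <- map_analogs(net, d, r, lambda = 0.95)
  expect_identical(unname(mp$winners$po[as.character(ids[[1]]["pr"])]),
                   ids[[2]][["pr"]])
  expect_identical(unname(mp$winners$po[as.character(ids[[1]]["ob"])]),
                   ids[[2]][["ob"]])
  expect_identical(unname(mp$winners$rb[as.character(ids[[1]]["rb"])]),
                   ids[[2]][["rb"]])
})

test_that("winner maps are one-to-one within every layer", {
  for (s in 1:5) {
    set.seed(s)
    f <- contains_fixture(b_term = "swap")
    mp <- map_analogs(f$net, f$driver, f$recipient, lambda = 0.7)
    for (ly in c("po", "rb", "p")) {
      w <- mp$winners[[ly]]
      expect_identical(anyDuplicated(unname(w)), 0L)
      expect_identical(anyDuplicated(names(w)), 0L)
    }
  }
})

test_that("mapping empty banks errors", {
  net <- dora_network(pool_size = 10)
  d <- add_analog(net, "driver"); r <- add_analog(net, "recipient")
  expect_error(map_analogs(net, d, r, 0.9), "non-empty")
})

test_that("the missing term is inferred by substitution into the mapped structure", {
  # A = contains(house, square), B = contains(square, shield),
  # C = contains(circle, triangle): the inferred D binds outside to
  # square's image (triangle) and inside to a newly recruited object
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    f <- contains_fixture(b_term = "shield")
    mp <- map_analogs(f$net, f$driver, f$recipient, lambda = 0.9,
                      props = f$p_a)
    ans <- infer_missing(f$net, mp, 0.9)
    expect_false(ans$empty)
    pr <- ans$inferred[[1]]
    expect_length(pr$pairs, 2)
    ok <- pr$pairs[[1]]$role == "outside" &&
      pr$pairs[[1]]$obj == f$triangle &&
      pr$pairs[[2]]$role == "inside" &&
      pr$pairs[[2]]$obj_recruited
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("a B term identical to A reproduces C's structure", {
  for (s in 1:5) {
    set.seed(s)
    f <- contains_fixture(b_term = "copy")
    mp <- map_analogs(f$net, f$driver, f$recipient, lambda = 0.9,
                      props = f$p_a)
    ans <- infer_missing(f$net, mp, 0.9)
    pr <- ans$inferred[[1]]
    expect_identical(pr$pairs[[1]]$obj, f$circle)
    expect_identical(pr$pairs[[2]]$obj, f$triangle)
    expect_false(any(vapply(pr$pairs, `[[`, logical(1), "obj_recruited")))
  }
})

test_that("inference is refused without any prior mapping", {
  f <- contains_fixture(b_term = "swap")
  mp <- map_analogs(f$net, f$driver, f$recipient, lambda = 0.9,
                    n_passes = 0)
  ans <- infer_missing(f$net, mp, 0.9)
  expect_true(ans$empty)
  expect_length(ans$inferred, 0)
})

test_that("structure is preserved when the mapping is complete and correct", {
  # the inferred D has the same RB count and role skeleton as B
  for (s in 1:5) {
    set.seed(s)
    f <- contains_fixture(b_term = "swap")
    mp <- map_analogs(f$net, f$driver, f$recipient, lambda = 0.95,
                      props = f$p_a)
    w <- mp$winners$po
    complete <- identical(unname(w[as.character(c(f$out_d, f$in_d,
                                                  f$house, f$square))]),
                          c(f$out_r, f$in_r, f$circle, f$triangle))
    if (!complete) next
    ans <- infer_missing(f$net, mp, 0.95)
    pr <- ans$inferred[[1]]
    expect_length(pr$pairs, 2)
    expect_identical(vapply(pr$pairs, `[[`, character(1), "role"),
                     c("outside", "inside"))
  }
})

test_that("inference accuracy degrades when inhibition collapses", {
  correct_at <- function(lambda, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      f <- contains_fixture(b_term = "swap", lambda = lambda)
      mp <- map_analogs(f$net, f$driver, f$recipient, lambda = lambda,
                        props = f$p_a)
      ans <- infer_missing(f$net, mp, lambda)
      if (ans$empty || !length(ans$inferred)) return(FALSE)
      pr <- ans$inferred[[1]]
      length(pr$pairs) == 2 &&
        identical(pr$pairs[[1]]$obj, f$triangle) &&
        identical(pr$pairs[[2]]$obj, f$circle)
    }, logical(1)))
  }
  lo <- correct_at(0.05, 1:100)
  hi <- correct_at(0.95, 1:100)
  expect_lt(lo, hi)
  expect_gt(hi, 0.9)
  expect_lt(lo, 0.4)
})
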