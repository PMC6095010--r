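# Encoding of A:B::C:D items over learned representations, end-to-end
# solving, and response classification.

# Encode a problem as a fresh network: A and B terms in the driver, C in
# the recipient.  Term objects are object POs with four idiosyncratic
# semantics; each transformation instance binds them to a learned
# transformation predicate retrieved from LTM under the individual's
# inhibition level (retrieval is itself a competition: weak inhibition
# retrieves relationally dirtier predicates).  A role for which no
# retrievable predicate exists is left unencoded — the term then carries
# object features only and that transformation cannot be inferred.
encode_problem <- function(problem, learning, n_avail, lambda,
                           config = dora_config()) {
  net <- dora_network(pool_size = learning$world$pool_size,
                      inhibition = lambda)
  driver <- add_analog(net, "driver")
  recipient <- add_analog(net, "recipient")
  roles_needed <- unique(unlist(lapply(problem$instances, function(inst) {
    if (inst$arity == 1L) inst$type else c("outside", "inside")
  })))
  retrieved <- lapply(roles_needed, function(role) {
    retrieve_predicate(learning, role, lambda, n_avail, config)
  })
  names(retrieved) <- roles_needed
  a_obj <- vapply(seq_len(problem$elements), function(i) {
    create_object(net, problem$a_features[[i]], driver,
                  meta = list(term = "A", local = i))
  }, integer(1))
  c_obj <- vapply(seq_len(problem$elements), function(i) {
    create_object(net, problem$c_features[[i]], recipient,
                  meta = list(term = "C", local = i))
  }, integer(1))
  mk_pred <- function(role, analog) {
    r <- retrieved[[role]]
    if (is.null(r)) return(NA_integer_)
    create_predicate(net, r$w, analog, meta = list(role = role))
  }
  a_props <- integer(0); b_props <- integer(0)
  for (inst in problem$instances) {
    if (inst$arity == 1L) {
      pd <- mk_pred(inst$type, driver)
      pr <- mk_pred(inst$type, recipient)
      if (is.na(pd) || is.na(pr)) next
      o <- inst$objects[1]
      a_props <- c(a_props,
                   make_proposition(net, list(c(pd, a_obj[o])), driver))
      b_props <- c(b_props,
                   make_proposition(net, list(c(pd, a_obj[o])), driver))
      make_proposition(net, list(c(pr, c_obj[o])), recipient)
    } else {
      od <- mk_pred("outside", driver); id_ <- mk_pred("inside", driver)
      or <- mk_pred("outside", recipient); ir <- mk_pred("inside", recipient)
      o1 <- inst$objects[1]; o2 <- inst$objects[2]
      bd <- list(); bb <- list(); bc <- list()
      if (!is.na(od) && !is.na(or)) {
        bd <- c(bd, list(c(od, a_obj[o1])))
        bb <- c(bb, list(c(od, a_obj[o2])))     # containment exchanged in B
        bc <- c(bc, list(c(or, c_obj[o1])))
      }
      if (!is.na(id_) && !is.na(ir)) {
        bd <- c(bd, list(c(id_, a_obj[o2])))
        bb <- c(bb, list(c(id_, a_obj[o1])))
        bc <- c(bc, list(c(ir, c_obj[o2])))
      }
      if (length(bd)) {
        a_props <- c(a_props, make_proposition(net, bd, driver))
        b_props <- c(b_props, make_proposition(net, bb, driver))
        make_proposition(net, bc, recipient)
      }
    }
  }
  list(net = net, driver = driver, recipient = recipient,
       a_props = a_props, b_props = b_props,
       a_objects = a_obj, c_objects = c_obj, retrieved = retrieved)
}

#' Solve one A:B::C:D analogy problem with learned representations
#'
#' The A and B terms are placed in the driver and the C term in the
#' recipient, each encoded as object POs with four idiosyncratic semantics
#' bound to transformation predicates retrieved from the learned LTM (the
#' A--C correspondence is never given: it must be discovered by the
#' mapping algorithm).  The A term is mapped onto C by [map_analogs()];
#' the B term, left without recipient counterparts, then drives
#' [infer_missing()], and the inferred recipient propositions are the
#' model's generated D term.
#'
#' @param problem a `dora_problem` from [generate_battery()].
#' @param learning a [learn_relations()] result.
#' @param checkpoint learning checkpoint whose representations are used.
#' @param lambda lateral inhibition for this trial, (0, 1].
#' @param config a [dora_config()].
#' @return A `dora_answer` with, additionally, the C-term object token ids
#'   (`c_objects`) needed to score the answer against the problem's
#'   correct D.
#' @export
solve_problem <- function(problem, learning, checkpoint, lambda,
                          config = dora_config()) {
  n_avail <- predicates_at(learning, checkpoint)
  enc <- encode_problem(problem, learning, n_avail, lambda, config)
  if (!length(enc$a_props) && !length(enc$b_props)) {
    ans <- structure(list(inferred = list(), empty = TRUE, winners = NULL),
                     class = "dora_answer")
    ans$c_objects <- enc$c_objects
    return(ans)
  }
  mp <- map_analogs(enc$net, enc$driver, enc$recipient, lambda,
                    n_passes = config$n_passes, config = config,
                    props = enc$a_props)
  ans <- infer_missing(enc$net, mp, lambda, config)
  ans$c_objects <- enc$c_objects
  ans
}

#' Classify a generated D term
#'
#' An answer is *analogical* when every required transformation is present
#' with the correct role-to-object assignment, *incomplete* when at least
#' one but not all transformations are correctly inferred, and
#' *associative* when none is (including empty answers and bare copies of
#' C or B objects without correct relational structure).  Transformation
#' instances of the same kind are interchangeable: matching is over the
#' set of inferred propositions.
#'
#' @param answer a `dora_answer` from [solve_problem()] (must carry
#'   `c_objects`).
#' @param problem the `dora_problem` that was solved.
#' @return A list with `outcome` (factor level), `n_correct` and
#'   `n_instances`.
#' @export
classify_response <- function(answer, problem) {
  c_obj <- answer$c_objects
  sig <- function(pairs) {
    paste(sort(vapply(pairs, function(pp) {
      paste0(pp$role, "|", pp$obj)
    }, character(1))), collapse = ";")
  }
  expected <- vapply(problem$correct_d, function(inst) {
    sig(lapply(inst$pairs, function(pp) {
      list(role = pp$role, obj = c_obj[pp$obj])
    }))
  }, character(1))
  got <- if (answer$empty) character(0) else {
    vapply(answer$inferred, function(pr) sig(pr$pairs), character(1))
  }
  n_correct <- 0L
  for (e in expected) {
    hit <- match(e, got)
    if (!is.na(hit)) {
      n_correct <- n_correct + 1L
      got <- got[-hit]
    }
  }
  n_inst <- length(expected)
  outcome <- if (n_correct == n_inst) "analogical"
  else if (n_correct >= 1L) "incomplete"
  else "associative"
  list(outcome = factor(outcome,
                        levels = c("analogical", "incomplete",
                                   "associative")),
       n_correct = n_correct, n_instances = n_inst)
}
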