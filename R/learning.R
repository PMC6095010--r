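# Comparison-based predicate discovery: co-activation of shared semantics,
# Hebbian recruitment of predicate POs and RBs, whole-relation formation,
# and the representation-quality metric.

as_weights <- function(x) {
  if (is.list(x) && !is.null(x$down)) return(x$down)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a token or a named weight vector")
}

#' Semantic co-activation under comparison
#'
#' When two items are compared they become co-active and pass activation to
#' their semantic features.  Features shared by both items receive input
#' from both and end up (roughly) twice as active as unshared features:
#' activations are the summed inputs normalised by the maximum possible
#' co-activation, so shared features sit at 1.0 and unshared ones at 0.5
#' for binary-coded objects.  If the items share nothing, all features are
#' equally (half) active and there is no structure to learn from.
#'
#' @param a,b object POs (tokens) or named weight vectors.
#' @return Named numeric vector of semantic activations in `[0, 1]`.
#' @examples
#' coactive_semantics(c("1" = 1, "2" = 1, "3" = 1),
#'                    c("2" = 1, "3" = 1, "4" = 1))
#' @export
coactive_semantics <- function(a, b) {
  wa <- as_weights(a)
  wb <- as_weights(b)
  ids <- union(names(wa), names(wb))
  inp <- stats::setNames(numeric(length(ids)), ids)
  inp[names(wa)] <- inp[names(wa)] + wa
  inp[names(wb)] <- inp[names(wb)] + wb
  denom <- max(wa, 0) + max(wb, 0)
  if (denom <= 0) return(inp)
  inp / denom
}

#' Recruit a predicate PO from the comparison of two items
#'
#' A new PO unit learns connections to the active semantics in proportion
#' to their activation via one saturating Hebbian pass:
#' \eqn{w(s) = \min(1, \gamma\, a(s))}.  The new unit therefore acquires
#' strong connections to the semantics the compared items share and weak
#' connections to the rest — an explicit, bindable representation of the
#' items' featural overlap.  When the network and analog are supplied, an
#' RB unit is also recruited linking the new predicate to each compared
#' object.
#'
#' @param a,b compared items (object POs, or already-learned predicates
#'   being refined): tokens or named weight vectors.
#' @param gamma Hebbian learning rate in (0, 1].
#' @param sharpness exponent applied to the semantic co-activations before
#'   the Hebbian pass.  1 (the default) reproduces the canonical
#'   twice-as-active pattern; larger values model stronger lateral
#'   inhibition among semantic units, which suppresses the unshared
#'   (weakly active) semantics and yields relationally cleaner predicates.
#'   [learn_relations()] sets this from the individual's inhibition level.
#' @param base starting connection weights the Hebbian pass accumulates
#'   onto (default none).  When an already-learned predicate is refined by
#'   a further comparison, its weights are the base, so the connection to
#'   semantics shared across `k` comparisons follows the saturating
#'   closed form `min(1, k * gamma)`.
#' @param decay fraction by which base connections to weakly co-active
#'   semantics decay per refinement (refinement sharpens as well as
#'   strengthens).
#' @param prune weights below this are dropped (sparse storage).
#' @param net,analog optionally, a [dora_network()] and analog id in which
#'   to recruit the predicate (and RBs when the compared items are tokens
#'   in `net`).
#' @return When `net` is `NULL`, the new predicate's named weight vector;
#'   otherwise a list with the new `pred` id and any recruited `rb` ids.
#' @export
predicate_from_comparison <- function(a, b, gamma = 1, sharpness = 1,
                                      base = NULL, decay = 0.5,
                                      prune = 0.01, net = NULL,
                                      analog = NULL) {
  act <- coactive_semantics(a, b)^sharpness
  w <- pmin(gamma * act, 1)
  if (!is.null(base)) {
    # accumulate onto the refined predicate: strongly co-active semantics
    # gain gamma per comparison (saturating at 1), weakly active ones
    # decay, so refinement sharpens as well as strengthens
    base <- as_weights(base)
    ids <- union(names(w), names(base))
    av <- stats::setNames(numeric(length(ids)), ids)
    av[names(act)] <- act
    acc <- stats::setNames(numeric(length(ids)), ids)
    acc[names(base)] <- base
    acc <- acc * (1 - decay * (1 - av))
    acc[names(w)] <- acc[names(w)] + w
    w <- pmin(acc, 1)
  }
  w <- w[w >= prune]
  if (is.null(net)) return(w)
  pred <- create_predicate(net, w, analog)
  rbs <- integer(0)
  for (item in list(a, b)) {
    if (is.list(item) && !is.null(item$id) && token_exists(net, item$id) &&
        identical(item$kind, "object")) {
      wrb <- c(1, 1)
      names(wrb) <- as.character(c(pred, item$id))
      rbs <- c(rbs, add_token(net, "RB", NA_character_, wrb, analog,
                              meta = list(pred = pred, obj = item$id)))
    }
  }
  list(pred = pred, rb = rbs)
}

#' Recruit a P unit over co-firing role-filler bindings
#'
#' When two or more role-filler sets are co-selected into working memory
#' and mapped across driver and recipient, the oscillating firing pattern
#' signals the model to recruit a P unit that links the active RBs
#' (saturating Hebbian updates, weight 1.0), yielding a multi-place
#' relational structure such as `contains(x, y)`.
#'
#' @param net a [dora_network()].
#' @param rb_ids ids of the co-firing RB units.
#' @param analog analog id for the new P unit.
#' @return The new P id, or `NULL` when fewer than two RBs are given
#'   (no-op).
#' @export
form_relation <- function(net, rb_ids, analog) {
  if (length(rb_ids) < 2) return(NULL)
  w <- rep(1, length(rb_ids))
  names(w) <- as.character(rb_ids)
  add_token(net, "P", NA_character_, w, analog,
            meta = list(rbs = as.integer(rb_ids)))
}

#' Representation quality of a learned predicate
#'
#' The mean of the connection weights to the relevant semantics (those
#' defining a specific transformation or transformation role) divided by
#' the mean of all other (nonzero) connection weights plus one; the +1
#' keeps the metric bounded in `[0, 1]`.
#'
#' @param pred a predicate PO token or named weight vector.
#' @param relevant_ids semantic ids defining the transformation or role.
#' @return Quality in `[0, 1]`.
#' @examples
#' quality(c("1" = 0.9, "2" = 0.8, "3" = 0.2, "4" = 0.2), c(1, 2))
#' @export
quality <- function(pred, relevant_ids) {
  if (is.list(pred) && identical(pred$kind, "object")) {
    stop("quality is defined for predicate POs, not objects")
  }
  w <- as_weights(pred)
  if (!length(relevant_ids)) stop("no relevant semantics given")
  relevant_ids <- as.character(relevant_ids)
  wr <- w[relevant_ids]
  wr[is.na(wr)] <- 0
  others <- setdiff(names(w)[w > 0], relevant_ids)
  denom <- (if (length(others)) mean(w[others]) else 0) + 1
  mean(wr) / denom
}

# quality of a weight vector against each of the six transformation roles
role_qualities <- function(w, roles = role_semantics()) {
  vapply(roles, function(ids) quality(w, ids), numeric(1))
}

# relevance: strongly connected (weight above threshold) to both defining
# semantics of some role
relevant_roles <- function(w, threshold, roles = role_semantics()) {
  names(roles)[vapply(roles, function(ids) {
    ww <- w[as.character(ids)]
    !anyNA(ww) && all(ww > threshold)
  }, logical(1))]
}

#' Run the unstructured relational-learning phase
#'
#' Starting from the raw object world, each learning trial samples between
#' two and six items from long-term memory, selects one pair for
#' comparison through the inhibition-controlled working-memory
#' competition (supports are the pairwise semantic overlaps), and recruits
#' a new predicate PO from the comparison.  After the initial uniform
#' phase, items are drawn from the relevant learned predicates with
#' probability `mix_relevant`, so learned representations feed later
#' comparisons and are gradually refined.  When a compared pair of objects
#' carries complementary containment roles, the two recruited RBs co-fire
#' and a P unit is formed over them (whole-relation learning).
#'
#' Under weak inhibition the pair competition is nearly random, so
#' featurally unrelated items are often compared and the resulting
#' predicates spread their weights over accidental overlap: this is the
#' mechanism by which low inhibitory control yields relationally imprecise
#' representations.
#'
#' Learned tokens are never modified afterwards (refinement recruits new
#' units and leaves the old ones in LTM), so a checkpoint is fully
#' described by the number of predicates learned so far.
#'
#' @param world a [generate_world()] object set.
#' @param lambda lateral inhibition of the simulated individual, (0, 1].
#' @param n_trials number of learning trials (at least `checkpoint_every`).
#' @param config a [dora_config()].
#' @return An object of class `dora_learning`: the learned predicates
#'   (weight vectors plus per-role quality), the relations formed, a
#'   checkpoint table (`trial`, `n_predicates`, `mean_quality`), and the
#'   settings used.  `mean_quality` is the expected quality, under the
#'   individual's own retrieval competition, of the predicate it would
#'   use for each transformation role, averaged over the six roles —
#'   the quality of the relational knowledge available for reasoning at
#'   that checkpoint.
#' @examples
#' set.seed(11)
#' w <- generate_world(n_objects = 20, pool_size = 300)
#' fit <- learn_relations(w, lambda = 0.8, n_trials = 100)
#' fit$checkpoints
#' @export
learn_relations <- function(world, lambda, n_trials = 800L,
                            config = dora_config()) {
  stopifnot(inherits(world, "dora_world"), lambda > 0, lambda <= 1)
  n_trials <- as.integer(n_trials)
  ck <- as.integer(config$checkpoint_every)
  if (n_trials < ck) stop("n_trials must be at least checkpoint_every")
  roles <- role_semantics()
  objs <- lapply(world$objects, `[[`, "w")
  n_obj <- length(objs)
  tau <- tau_lambda(lambda, config$epsilon_tau)
  kmin <- config$items_per_trial[1]
  kmax <- config$items_per_trial[2]

  preds <- vector("list", n_trials)
  pred_q <- matrix(NA_real_, n_trials, length(roles),
                   dimnames = list(NULL, names(roles)))
  best_q <- numeric(n_trials)
  relevant_idx <- integer(0)
  n_pred <- 0L
  relations <- list()
  checkpoints <- data.frame(trial = integer(0), n_predicates = integer(0),
                            mean_quality = numeric(0))

  obj_norm <- vapply(objs, function(w) sqrt(sum(w^2)), numeric(1))
  pred_norm <- numeric(n_trials)
  sharp <- 1 / (tau + config$sharpness_floor)

  for (trial in seq_len(n_trials)) {
    k <- sample(seq.int(kmin, kmax), 1L)
    items <- vector("list", k)
    item_obj <- integer(k)          # object index or 0 for a predicate
    item_pred <- integer(k)         # predicate index or 0 for an object
    for (i in seq_len(k)) {
      if (trial > config$uniform_phase && length(relevant_idx) &&
          stats::runif(1) < config$mix_relevant) {
        pick <- relevant_idx[sample.int(length(relevant_idx), 1L)]
        items[[i]] <- preds[[pick]]$w
        item_pred[i] <- pick
      } else if (n_pred > 0L &&
                 (j <- sample.int(n_obj + n_pred, 1L)) > n_obj) {
        items[[i]] <- preds[[j - n_obj]]$w
        item_pred[i] <- j - n_obj
      } else {
        oi <- sample.int(n_obj, 1L)
        items[[i]] <- objs[[oi]]
        item_obj[i] <- oi
      }
    }
    # working-memory competition over candidate pairs; supports are the
    # pairwise similarities (normalised semantic overlap)
    if (k == 2L) {
      pair <- c(1L, 2L)
    } else {
      nrm <- ifelse(item_pred > 0L, pred_norm[pmax(item_pred, 1L)],
                    obj_norm[pmax(item_obj, 1L)])
      cmb <- utils::combn(k, 2L)
      supp <- config$support_gain * vapply(seq_len(ncol(cmb)), function(j) {
        d <- nrm[cmb[1, j]] * nrm[cmb[2, j]]
        if (d > 0) sem_dot(items[[cmb[1, j]]], items[[cmb[2, j]]]) / d else 0
      }, numeric(1))
      names(supp) <- seq_len(ncol(cmb))
      j <- as.integer(select_for_wm(supp, lambda))
      pair <- cmb[, j]
    }
    # refinement: when a learned predicate takes part in the comparison it
    # is the base the Hebbian pass accumulates onto (for two predicates,
    # the relationally cleaner one); object-object pairs recruit afresh
    base <- NULL
    if (any(item_pred[pair] > 0L)) {
      cand <- item_pred[pair][item_pred[pair] > 0L]
      base <- preds[[cand[which.max(best_q[cand])]]]$w
    }
    w_new <- predicate_from_comparison(items[[pair[1]]], items[[pair[2]]],
                                       gamma = config$gamma,
                                       sharpness = sharp, base = base,
                                       decay = config$refine_decay,
                                       prune = config$prune_weight)
    if (length(w_new)) {  # a comparison can leave nothing to recruit from
      n_pred <- n_pred + 1L
      pred_norm[n_pred] <- sqrt(sum(w_new^2))
      q <- role_qualities(w_new, roles)
      rel <- relevant_roles(w_new, config$relevance_threshold, roles)
      preds[[n_pred]] <- list(w = w_new, trial = trial,
                              parents = item_obj[pair], relevant = rel)
      pred_q[n_pred, ] <- q
      best_q[n_pred] <- max(q)
      if (length(rel)) relevant_idx <- c(relevant_idx, n_pred)
      # whole-relation formation: compared objects carrying complementary
      # containment roles put two role-filler bindings into WM together
      if (all(item_obj[pair] > 0L)) {
        r1 <- world$objects[[item_obj[pair[1]]]]$roles
        r2 <- world$objects[[item_obj[pair[2]]]]$roles
        if (("outside" %in% r1 && "inside" %in% r2) ||
            ("inside" %in% r1 && "outside" %in% r2)) {
          relations[[length(relations) + 1L]] <-
            list(pred = n_pred, objects = item_obj[pair], trial = trial)
        }
      }
    }
    if (trial %% ck == 0L) {
      checkpoints <- rbind(checkpoints, data.frame(
        trial = trial, n_predicates = n_pred,
        mean_quality = NA_real_))
    }
  }

  # checkpoint quality: for each transformation role, the expected quality
  # of the predicate the individual would retrieve for it (softmax over
  # candidate qualities at the individual's inhibition), averaged over
  # roles.  This measures the representations actually available for
  # reasoning, not the cumulative archive of every comparison ever made.
  qmat <- pred_q[seq_len(n_pred), , drop = FALSE]
  cand_ok <- vapply(names(roles), function(role) {
    ids <- as.character(roles[[role]])
    vapply(seq_len(n_pred), function(i) {
      w <- preds[[i]]$w[ids]
      !anyNA(w) && all(w > config$candidate_min_weight)
    }, logical(1))
  }, logical(n_pred))
  for (r in seq_len(nrow(checkpoints))) {
    n <- checkpoints$n_predicates[r]
    checkpoints$mean_quality[r] <- mean(vapply(seq_along(roles), function(j) {
      cand <- which(cand_ok[seq_len(n), j])
      if (!length(cand)) return(0)
      q <- qmat[cand, j]
      z <- exp(config$retrieval_gain * (q - max(q)) / tau)
      sum(z * q) / sum(z)
    }, numeric(1)))
  }

  structure(list(
    predicates = preds[seq_len(n_pred)],
    quality_by_role = pred_q[seq_len(n_pred), , drop = FALSE],
    relations = relations,
    checkpoints = checkpoints,
    lambda = lambda,
    n_trials = n_trials,
    config = config,
    world = world
  ), class = "dora_learning")
}

#' @export
print.dora_learning <- function(x, ...) {
  cat("Relational learning run: lambda =", format(x$lambda), "over",
      x$n_trials, "trials\n")
  cat("  predicates learned:", length(x$predicates),
      " relations formed:", length(x$relations), "\n")
  cat("  mean representation quality at checkpoints:\n")
  print(x$checkpoints, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dora_learning <- function(x, ...) {
  graphics::plot(x$checkpoints$trial, x$checkpoints$mean_quality, type = "b",
                 xlab = "learning trial", ylab = "mean representation quality",
                 ylim = c(0, 1), pch = 16,
                 main = sprintf("Relational learning (lambda = %.2f)",
                                x$lambda), ...)
  invisible(x)
}

# number of predicates available at a given checkpoint trial
predicates_at <- function(learning, checkpoint) {
  row <- learning$checkpoints[learning$checkpoints$trial == checkpoint, ]
  if (!nrow(row)) {
    stop("no checkpoint at trial ", checkpoint, " (trained to ",
         learning$n_trials, " trials)")
  }
  row$n_predicates[1]
}

# Inhibition-controlled retrieval of a learned predicate for a role:
# candidates are predicates connected above `candidate_min_weight` to both
# defining semantics; the retrieval competition is a softmax over their
# qualities with temperature tau(lambda).  NULL when nothing qualifies.
retrieve_predicate <- function(learning, role, lambda, n_avail,
                               config = learning$config) {
  if (!n_avail) return(NULL)
  roles <- role_semantics()
  ids <- as.character(roles[[role]])
  cand <- which(vapply(seq_len(n_avail), function(i) {
    w <- learning$predicates[[i]]$w[ids]
    !anyNA(w) && all(w > config$candidate_min_weight)
  }, logical(1)))
  if (!length(cand)) return(NULL)
  q <- config$retrieval_gain * learning$quality_by_role[cand, role]
  names(q) <- cand
  pick <- as.integer(select_for_wm(q, lambda))
  list(index = pick, w = learning$predicates[[pick]]$w,
       quality = unname(learning$quality_by_role[pick, role]))
}

#' Convert a learning run into a LISAese network
#'
#' Materialises the object world and every predicate, RB and P learned up
#' to a checkpoint as tokens of a long-term-memory analog, for inspection
#' or JSON checkpointing via [serialize_network()].
#'
#' @param learning a [learn_relations()] result.
#' @param checkpoint checkpoint trial (defaults to the final one).
#' @return A [dora_network()].
#' @export
learning_to_network <- function(learning,
                                checkpoint = learning$n_trials) {
  n_avail <- predicates_at(learning, checkpoint)
  net <- dora_network(pool_size = learning$world$pool_size,
                      inhibition = learning$lambda)
  ltm <- add_analog(net, "ltm")
  obj_ids <- vapply(learning$world$objects, function(o) {
    add_token(net, "PO", "object", o$w, ltm)
  }, integer(1))
  pred_rbs <- vector("list", n_avail)
  for (i in seq_len(n_avail)) {
    p <- learning$predicates[[i]]
    pid <- create_predicate(net, p$w, ltm,
                            meta = list(trial = p$trial))
    rbs <- integer(0)
    for (oi in p$parents[p$parents > 0L]) {
      wrb <- c(1, 1)
      names(wrb) <- as.character(c(pid, obj_ids[oi]))
      rbs <- c(rbs, add_token(net, "RB", NA_character_, wrb, ltm,
                              meta = list(pred = pid, obj = obj_ids[oi])))
    }
    pred_rbs[[i]] <- rbs
  }
  for (rel in learning$relations) {
    if (rel$pred <= n_avail && length(pred_rbs[[rel$pred]]) >= 2) {
      form_relation(net, pred_rbs[[rel$pred]], ltm)
    }
  }
  net
}
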