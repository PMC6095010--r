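# Analogical mapping between driver and recipient banks, and
# self-supervised inference of the missing D term.
#
# Mapping connections are learned Hebbianly while driver propositions fire
# their asynchronous schedules and recipient units compete to respond.
# During mapping, recipient object candidates receive structural support
# from the role-binding that responded in the directly preceding role slot
# (this is what lets featurally disjoint fillers map through their shared
# roles).  During inference, images are driven by the learned mapping
# connections instead: an unmapped driver unit whose firing leaves no
# recipient unit above the winner threshold triggers recruitment of a new
# recipient unit mirroring it.

build_ctx <- function(net, driver, recipient) {
  ctx <- list(
    d_pred = analog_tokens(net, driver, "PO", "predicate"),
    d_obj  = analog_tokens(net, driver, "PO", "object"),
    d_rb   = analog_tokens(net, driver, "RB"),
    d_p    = analog_tokens(net, driver, "P"),
    r_pred = analog_tokens(net, recipient, "PO", "predicate"),
    r_obj  = analog_tokens(net, recipient, "PO", "object"),
    r_rb   = analog_tokens(net, recipient, "RB"),
    r_p    = analog_tokens(net, recipient, "P")
  )
  ctx$rb_pred <- vapply(ctx$r_rb, function(i) net$tokens[[i]]$meta$pred,
                        integer(1))
  ctx$rb_obj <- vapply(ctx$r_rb, function(i) net$tokens[[i]]$meta$obj,
                       integer(1))
  ctx$rb_p <- rep(NA_integer_, length(ctx$r_rb))
  if (length(ctx$r_p)) {
    for (pi in seq_along(ctx$r_p)) {
      kids <- net$tokens[[ctx$r_p[pi]]]$meta$rbs
      ctx$rb_p[match(kids, ctx$r_rb)] <- ctx$r_p[pi]
    }
  }
  # driver top-level propositions: P units plus RBs not under any P
  under_p <- unlist(lapply(ctx$d_p, function(i) net$tokens[[i]]$meta$rbs))
  ctx$d_props <- c(ctx$d_p, setdiff(ctx$d_rb, under_p))
  ctx
}

empty_matrix <- function(rows, cols) {
  matrix(0, length(rows), length(cols),
         dimnames = list(as.character(rows), as.character(cols)))
}

# subtractive-normalised Hebbian update of one row of a mapping matrix:
# delta = eta * (a_r - max over competing hypotheses in the same row/column)
map_update <- function(m, u, act, eta) {
  cols <- names(act)
  if (!length(cols) || !nrow(m)) return(m)
  u <- as.character(u)
  row <- m[u, cols]
  col_other <- if (nrow(m) > 1) {
    apply(m[setdiff(rownames(m), u), cols, drop = FALSE], 2, max)
  } else rep(0, length(cols))
  row_other <- vapply(seq_along(cols), function(j) max(row[-j], 0), numeric(1))
  other <- pmax(row_other, col_other)
  m[u, cols] <- pmin(1, pmax(0, row + eta * (act - other)))
  m
}

# one-to-one winner extraction: greedy by weight, ties broken by weight
# then lowest driver id then lowest recipient id
layer_winners <- function(m, min_weight) {
  if (!length(m) || !nrow(m) || !ncol(m)) {
    return(stats::setNames(integer(0), character(0)))
  }
  idx <- which(m >= min_weight, arr.ind = TRUE)
  if (!nrow(idx)) return(stats::setNames(integer(0), character(0)))
  w <- m[idx]
  dn <- as.integer(rownames(m)[idx[, 1]])
  rn <- as.integer(colnames(m)[idx[, 2]])
  ord <- order(-w, dn, rn)
  taken_d <- character(0); taken_r <- character(0)
  win <- integer(0)
  for (i in ord) {
    d <- as.character(dn[i]); r <- as.character(rn[i])
    if (d %in% taken_d || r %in% taken_r) next
    win[d] <- rn[i]
    taken_d <- c(taken_d, d); taken_r <- c(taken_r, r)
  }
  win
}

#' Map a driver analog onto a recipient analog
#'
#' Runs `n_passes` full driver cycles.  In each cycle, driver propositions
#' are repeatedly selected for working memory through the
#' inhibition-controlled competition (supports decay with firing recency);
#' the selected proposition fires its asynchronous schedule, recipient
#' units compete to respond slot by slot, and mapping connections between
#' co-active units are updated Hebbianly with subtractive normalisation
#' against competing hypotheses.  Winner maps per layer are one-to-one.
#'
#' @param net a [dora_network()].
#' @param driver,recipient analog ids; both banks must be non-empty.
#' @param lambda lateral inhibition in (0, 1].
#' @param n_passes full driver cycles.
#' @param config a [dora_config()].
#' @param props optional subset of driver proposition ids to fire (defaults
#'   to every top-level proposition in the driver).
#' @return An object of class `dora_mapping` with mapping matrices `po`,
#'   `rb`, `p`, their one-to-one `winners`, and the context needed for
#'   inference.
#' @export
map_analogs <- function(net, driver, recipient, lambda = net$inhibition,
                        n_passes = 3L, config = dora_config(),
                        props = NULL) {
  if (!length(analog_tokens(net, driver)) ||
      !length(analog_tokens(net, recipient))) {
    stop("driver and recipient banks must be non-empty")
  }
  ctx <- build_ctx(net, driver, recipient)
  if (is.null(props)) props <- ctx$d_props
  m_po <- empty_matrix(c(ctx$d_pred, ctx$d_obj), c(ctx$r_pred, ctx$r_obj))
  m_rb <- empty_matrix(ctx$d_rb, ctx$r_rb)
  m_p <- empty_matrix(ctx$d_p, ctx$r_p)
  st <- new.env(parent = emptyenv())
  st$po <- m_po; st$rb <- m_rb; st$p <- m_p

  if (length(props)) {
    fires <- stats::setNames(rep(0, length(props)), as.character(props))
    for (step in seq_len(n_passes * length(props))) {
      supp <- config$recency_decay^fires
      sel <- select_for_wm(supp, lambda)
      fires[sel] <- fires[sel] + 1
      fire_prop_mapping(net, as.integer(sel), ctx, st, lambda, config)
    }
  }
  structure(list(
    po = st$po, rb = st$rb, p = st$p,
    winners = list(
      po = layer_winners(st$po, config$min_map_weight),
      rb = layer_winners(st$rb, config$min_map_weight),
      p = layer_winners(st$p, config$min_map_weight)
    ),
    driver = driver, recipient = recipient, lambda = lambda,
    ctx = ctx
  ), class = "dora_mapping")
}

#' @export
print.dora_mapping <- function(x, ...) {
  cat("Analogical mapping (lambda =", format(x$lambda), ")\n")
  for (ly in c("po", "rb", "p")) {
    w <- x$winners[[ly]]
    if (length(w)) {
      cat(" ", toupper(ly), "winners:",
          paste(names(w), "->", w, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# fire one driver proposition's schedule and update mapping connections
fire_prop_mapping <- function(net, prop, ctx, st, lambda, config) {
  slots <- fire_sequence(net, prop)
  nu <- config$noise_scale * tau_lambda(lambda, config$epsilon_tau)^config$noise_power
  rb_act_prev <- stats::setNames(rep(0, length(ctx$r_rb)),
                                 as.character(ctx$r_rb))
  p_act <- stats::setNames(rep(0, length(ctx$r_p)), as.character(ctx$r_p))
  for (slot in slots) {
    u <- slot$po
    w_u <- net$tokens[[u]]$down
    cands <- if (slot$po_role == "role") ctx$r_pred else ctx$r_obj
    if (!length(cands)) { rb_act_prev[] <- 0; next }
    # raw input: sum of shared-semantic weights, so weakly learned
    # predicates impose only a weak pattern on the recipient
    base <- vapply(cands, function(r) {
      sem_dot(w_u, net$tokens[[r]]$down)
    }, numeric(1))
    feed <- config$map_feed * st$po[as.character(u), as.character(cands)]
    struct <- if (slot$po_role == "filler") {
      config$struct_support * vapply(cands, function(r) {
        prbs <- ctx$r_rb[ctx$rb_obj == r]
        if (!length(prbs)) 0 else max(rb_act_prev[as.character(prbs)])
      }, numeric(1))
    } else {
      config$p_support * vapply(cands, function(r) {
        prbs <- ctx$r_rb[ctx$rb_pred == r]
        ps <- ctx$rb_p[match(prbs, ctx$r_rb)]
        ps <- ps[!is.na(ps)]
        if (!length(ps)) 0 else max(p_act[as.character(ps)])
      }, numeric(1))
    }
    input <- base + feed + struct + stats::runif(length(cands), 0, nu)
    leak <- stats::runif(1, 0, nu)
    act_all <- divisive_competition(c(input, leak), lambda)
    act <- stats::setNames(act_all[seq_along(cands)], as.character(cands))
    st$po <- map_update(st$po, u, act, config$eta)
    # RB layer: the pair's RB is active in the driver across both slots;
    # a recipient RB responds as strongly as its child in this slot
    rb_act <- stats::setNames(rep(0, length(ctx$r_rb)),
                              as.character(ctx$r_rb))
    child <- if (slot$po_role == "role") ctx$rb_pred else ctx$rb_obj
    hit <- match(child, cands)
    rb_act[!is.na(hit)] <- act[hit[!is.na(hit)]]
    if (length(ctx$r_rb)) {
      st$rb <- map_update(st$rb, slot$rb, rb_act, config$eta)
    }
    # P layer: the driver P (when present) is active throughout
    if (!is.na(slot$p) && length(ctx$r_p)) {
      p_now <- vapply(ctx$r_p, function(pp) {
        kids <- net$tokens[[pp]]$meta$rbs
        max(rb_act[as.character(kids)], 0)
      }, numeric(1))
      names(p_now) <- as.character(ctx$r_p)
      p_act <- pmax(p_act, p_now)
      st$p <- map_update(st$p, slot$p, p_now, config$eta)
    }
    rb_act_prev <- rb_act
  }
  invisible(NULL)
}

#' Self-supervised inference of unmapped driver structure
#'
#' Driver propositions left without a mapping winner (the B term, once A
#' has mapped to C) fire one by one.  Each firing unit activates recipient
#' candidates through its semantic footprint and its mapping connections;
#' recipient units already claimed by other driver units are suppressed.
#' If no unit responds above the winner threshold, a new recipient unit is
#' recruited mirroring the driver unit (predicates copy their semantics;
#' objects are new blank POs inheriting the driver object's semantics at
#' reduced weight), and RB/P units are recruited over the resulting
#' images.  The recruited-or-matched propositions are the model's answer.
#'
#' @param net a [dora_network()] (recruits are added to the recipient).
#' @param mapping a [map_analogs()] result.
#' @param lambda lateral inhibition in (0, 1].
#' @param config a [dora_config()].
#' @return An object of class `dora_answer`: `inferred` (a list of
#'   propositions, each with role/filler pairs and recruitment flags) and
#'   `empty` (`TRUE` when inference was refused because no mapping
#'   existed).
#' @export
infer_missing <- function(net, mapping, lambda = mapping$lambda,
                          config = dora_config()) {
  ctx <- mapping$ctx
  win_po <- mapping$winners$po
  if (!length(win_po)) {
    return(structure(list(inferred = list(), empty = TRUE,
                          winners = mapping$winners),
                     class = "dora_answer"))
  }
  top_win <- c(mapping$winners$p, mapping$winners$rb)
  unmapped <- ctx$d_props[!as.character(ctx$d_props) %in% names(top_win)]
  inferred <- list()
  if (length(unmapped)) {
    fires <- stats::setNames(rep(0, length(unmapped)),
                             as.character(unmapped))
    for (k in seq_along(unmapped)) {
      supp <- config$recency_decay^fires
      supp <- supp[fires == 0]
      sel <- as.integer(select_for_wm(supp, lambda))
      fires[as.character(sel)] <- 1
      inferred[[length(inferred) + 1L]] <-
        infer_prop(net, sel, ctx, mapping, lambda, config)
    }
  }
  structure(list(inferred = inferred, empty = FALSE,
                 winners = mapping$winners),
            class = "dora_answer")
}

#' @export
print.dora_answer <- function(x, ...) {
  if (x$empty) {
    cat("Inferred answer: none (no mapping established)\n")
    return(invisible(x))
  }
  cat("Inferred answer:", length(x$inferred), "proposition(s)\n")
  for (pr in x$inferred) {
    cat(" ", paste(vapply(pr$pairs, function(pp) {
      sprintf("%s(%s%s)", ifelse(is.na(pp$role), "?", pp$role), pp$obj,
              if (pp$obj_recruited) "*" else "")
    }, character(1)), collapse = " + "), "\n")
  }
  invisible(x)
}

# fire one unmapped driver proposition and construct its recipient image
infer_prop <- function(net, prop, ctx, mapping, lambda, config) {
  slots <- fire_sequence(net, prop)
  nu <- config$noise_scale * tau_lambda(lambda, config$epsilon_tau)^config$noise_power
  win_po <- mapping$winners$po
  pairs <- list()
  rb_imgs <- integer(0)
  rb_new <- FALSE
  i <- 1L
  while (i < length(slots)) {
    role_slot <- slots[[i]]; fill_slot <- slots[[i + 1L]]
    img_p <- infer_image(net, role_slot$po, ctx$r_pred, win_po,
                         mapping, lambda, nu, config)
    img_o <- infer_image(net, fill_slot$po, ctx$r_obj, win_po,
                         mapping, lambda, nu, config)
    if (img_p$recruit) {
      u <- net$tokens[[role_slot$po]]
      role <- if (!is.null(u$meta$role)) u$meta$role else NA_character_
      img_p$id <- create_predicate(net, u$down, mapping$recipient,
                                   meta = list(role = role,
                                               recruited = TRUE))
    }
    if (img_o$recruit) {
      u <- net$tokens[[fill_slot$po]]
      w <- pmin(config$recruit_sem_weight * u$down, 1)
      img_o$id <- add_token(net, "PO", "object", w, mapping$recipient,
                            meta = list(recruited = TRUE))
    }
    # reuse an existing recipient RB over exactly these children, if any
    have <- ctx$r_rb[ctx$rb_pred == img_p$id & ctx$rb_obj == img_o$id]
    if (length(have)) {
      rb_id <- have[1]
    } else {
      wrb <- c(1, 1)
      names(wrb) <- as.character(c(img_p$id, img_o$id))
      rb_id <- add_token(net, "RB", NA_character_, wrb, mapping$recipient,
                         meta = list(pred = img_p$id, obj = img_o$id,
                                     recruited = TRUE))
      rb_new <- TRUE
    }
    rb_imgs <- c(rb_imgs, rb_id)
    role <- net$tokens[[img_p$id]]$meta$role
    pairs[[length(pairs) + 1L]] <- list(
      role = if (is.null(role)) NA_character_ else role,
      pred = img_p$id, obj = img_o$id,
      pred_recruited = img_p$recruit, obj_recruited = img_o$recruit)
    i <- i + 2L
  }
  p_id <- NA_integer_
  if (length(rb_imgs) >= 2) {
    p_id <- if (rb_new) {
      form_relation(net, rb_imgs, mapping$recipient)
    } else {
      ex <- ctx$r_p[vapply(ctx$r_p, function(pp) {
        setequal(net$tokens[[pp]]$meta$rbs, rb_imgs)
      }, logical(1))]
      if (length(ex)) ex[1] else form_relation(net, rb_imgs,
                                               mapping$recipient)
    }
  }
  list(driver_prop = prop, pairs = pairs, rbs = rb_imgs, p = p_id)
}

# image of one firing driver PO during inference: semantic input plus
# mapping-connection feed, with units claimed by other drivers suppressed
infer_image <- function(net, u, cands, win_po, mapping, lambda, nu, config) {
  uc <- as.character(u)
  own <- if (uc %in% names(win_po)) win_po[[uc]] else NA_integer_
  free <- vapply(cands, function(r) {
    !(r %in% win_po) || identical(own, r)
  }, logical(1))
  cands <- cands[free]
  if (length(cands)) {
    w_u <- net$tokens[[u]]$down
    base <- vapply(cands, function(r) {
      sem_dot(w_u, net$tokens[[r]]$down)
    }, numeric(1))
    feed <- config$map_feed * mapping$po[uc, as.character(cands)]
    input <- base + feed + stats::runif(length(cands), 0, nu)
    leak <- stats::runif(1, 0, nu)
    act_all <- divisive_competition(c(input, leak), lambda)
    act <- act_all[seq_along(cands)]
    j <- which.max(act)
    if (act[j] >= config$winner_threshold) {
      return(list(id = cands[j], recruit = FALSE))
    }
  }
  list(id = NA_integer_, recruit = TRUE)
}
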