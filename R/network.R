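# --- sparse semantic weight helpers -----------------------------------------
# Weight vectors are named numerics: names are semantic ids ("0".."pool-1")
# for PO units, or token ids for RB/P units.  Absent names mean weight 0.

sem_dot <- function(w1, w2) {
  common <- intersect(names(w1), names(w2))
  if (!length(common)) return(0)
  sum(w1[common] * w2[common])
}

#' Create an empty LISAese network
#'
#' A network holds the shared semantic pool, the token hierarchy (PO, RB and
#' P units grouped into analogs), and the lateral-inhibition level of the
#' simulated individual.  Tokens carry weighted connections only to the layer
#' directly beneath them; the layering is checked on every mutation.
#'
#' @param pool_size number of semantic units in the shared pool.  Semantic
#'   ids are integers in `[0, pool_size)`.
#' @param inhibition lateral-inhibition level \eqn{\lambda} in (0, 1].
#'
#' @return An environment of class `dora_network`.
#' @examples
#' net <- dora_network(pool_size = 50, inhibition = 0.8)
#' a <- add_analog(net, "driver")
#' o <- create_object(net, c(3, 7), analog = a)
#' get_token(net, o)$down
#' @export
dora_network <- function(pool_size = 1000L, inhibition = 0.8) {
  stopifnot(pool_size >= 1, inhibition > 0, inhibition <= 1)
  net <- new.env(parent = emptyenv())
  net$pool_size <- as.integer(pool_size)
  net$inhibition <- inhibition
  net$next_id <- 1L
  net$tokens <- list()
  net$analogs <- list()
  net$next_analog <- 1L
  class(net) <- "dora_network"
  net
}

#' @export
print.dora_network <- function(x, ...) {
  layers <- vapply(x$tokens, function(t) t$layer, character(1))
  cat("LISAese network: pool of", x$pool_size, "semantics, lambda =",
      format(x$inhibition), "\n")
  cat("  tokens:", length(x$tokens),
      sprintf("(PO %d, RB %d, P %d)", sum(layers == "PO"),
              sum(layers == "RB"), sum(layers == "P")), "\n")
  cat("  analogs:", length(x$analogs), "\n")
  invisible(x)
}

#' Add an analog (bank of tokens) to a network
#'
#' @param net a [dora_network()].
#' @param role one of `"driver"`, `"recipient"`, `"ltm"`.  Driver and
#'   recipient are mutually exclusive banks; every token belongs to exactly
#'   one analog.
#' @return The integer analog id.
#' @export
add_analog <- function(net, role = c("ltm", "driver", "recipient")) {
  role <- match.arg(role)
  id <- net$next_analog
  net$next_analog <- id + 1L
  net$analogs[[id]] <- list(id = id, role = role, tokens = integer(0))
  id
}

issue_id <- function(net) {
  id <- net$next_id
  net$next_id <- id + 1L
  id
}

#' Retrieve a token by id
#' @param net a [dora_network()].
#' @param id integer token id.
#' @return The token, a list with fields `id`, `layer`, `kind`, `down`,
#'   `analog` and `meta`.
#' @export
get_token <- function(net, id) {
  tok <- if (id >= 1 && id <= length(net$tokens)) net$tokens[[id]] else NULL
  if (is.null(tok)) stop("no token with id ", id)
  tok
}

token_exists <- function(net, id) {
  id >= 1 && id <= length(net$tokens) && !is.null(net$tokens[[id]])
}

check_weights <- function(w) {
  if (length(w)) {
    if (is.null(names(w)) || any(!nzchar(names(w)))) {
      stop("connection weights must be named")
    }
    if (any(w < 0 | w > 1)) stop("connection weights must lie in [0, 1]")
  }
  invisible(w)
}

# Layering invariant: PO -> semantics only, RB -> exactly one predicate PO
# and one object PO, P -> RBs only.  Checked on every token insertion.
check_layering <- function(net, layer, kind, down) {
  ids <- names(down)
  if (layer == "PO") {
    sem <- suppressWarnings(as.integer(ids))
    if (length(ids) && (any(is.na(sem)) || any(sem < 0) ||
                        any(sem >= net$pool_size))) {
      stop("PO units may only connect to semantic ids in [0, pool_size)")
    }
    if (!kind %in% c("object", "predicate")) {
      stop("PO units must be objects or predicates")
    }
  } else if (layer == "RB") {
    if (length(ids) != 2) {
      stop("an RB must connect exactly one predicate PO and one object PO")
    }
    kids <- lapply(as.integer(ids), function(i) {
      if (!token_exists(net, i)) stop("RB child ", i, " does not exist")
      get_token(net, i)
    })
    if (any(vapply(kids, function(k) k$layer, character(1)) != "PO")) {
      stop("RB units may only connect to PO units")
    }
    kinds <- sort(vapply(kids, function(k) k$kind, character(1)))
    if (!identical(kinds, c("object", "predicate"))) {
      stop("an RB must connect exactly one predicate PO and one object PO")
    }
  } else if (layer == "P") {
    if (!length(ids)) stop("a P unit must connect to at least one RB")
    for (i in as.integer(ids)) {
      if (!token_exists(net, i) || get_token(net, i)$layer != "RB") {
        stop("P units may only connect to RB units")
      }
    }
  } else {
    stop("unknown layer: ", layer)
  }
  invisible(TRUE)
}

add_token <- function(net, layer, kind = NA_character_, down = numeric(0),
                      analog, meta = list()) {
  if (!analog %in% seq_along(net$analogs)) stop("unknown analog ", analog)
  check_weights(down)
  check_layering(net, layer, kind, down)
  id <- issue_id(net)
  net$tokens[[id]] <- list(id = id, layer = layer, kind = kind,
                           down = down, analog = as.integer(analog),
                           meta = meta)
  net$analogs[[analog]]$tokens <- c(net$analogs[[analog]]$tokens, id)
  id
}

#' Create an object PO from a set of semantic features
#'
#' The object is connected with weight 1 to each listed semantic unit and to
#' nothing else, mirroring a flat, holistic feature-vector representation.
#'
#' @param net a [dora_network()].
#' @param semantic_ids integer semantic ids in `[0, pool_size)`; non-empty.
#' @param analog analog id the object belongs to.
#' @param meta optional metadata list stored on the token.
#' @return The new token id.
#' @export
create_object <- function(net, semantic_ids, analog, meta = list()) {
  if (!length(semantic_ids)) stop("an object needs at least one semantic")
  semantic_ids <- as.integer(semantic_ids)
  if (anyNA(semantic_ids) || any(semantic_ids < 0) ||
      any(semantic_ids >= net$pool_size)) {
    stop("semantic ids must lie in [0, pool_size)")
  }
  if (anyDuplicated(semantic_ids)) stop("duplicated semantic ids")
  w <- rep(1, length(semantic_ids))
  names(w) <- as.character(semantic_ids)
  add_token(net, "PO", "object", w, analog, meta)
}

#' Create a predicate PO with explicit connection weights
#'
#' @param net a [dora_network()].
#' @param weights named numeric vector of connection weights to semantic
#'   ids, all in `[0, 1]`.
#' @param analog analog id.
#' @param meta optional metadata list (for instance the role the predicate
#'   is taken to express).
#' @return The new token id.
#' @export
create_predicate <- function(net, weights, analog, meta = list()) {
  add_token(net, "PO", "predicate", weights, analog, meta)
}

#' Build a proposition from ordered role-filler bindings
#'
#' Each binding recruits an RB unit connecting one predicate PO to one
#' object PO; two or more bindings are linked by a P unit.  A single binding
#' yields a lone RB (single-place predicate structure) and no P unit.
#'
#' @param net a [dora_network()].
#' @param bindings list of length-2 integer vectors `c(predicate_id,
#'   object_id)`, in role order.
#' @param analog analog id for the recruited RB/P units.
#' @return The id of the P unit, or of the RB when only one binding is
#'   given.
#' @examples
#' net <- dora_network(pool_size = 20)
#' a <- add_analog(net, "driver")
#' house <- create_object(net, c(12, 13), a)
#' square <- create_object(net, c(14, 15), a)
#' outside <- create_predicate(net, c("0" = 1, "1" = 1), a)
#' inside <- create_predicate(net, c("2" = 1, "3" = 1), a)
#' p <- make_proposition(net, list(c(outside, house), c(inside, square)), a)
#' get_token(net, p)$layer
#' @export
make_proposition <- function(net, bindings, analog) {
  if (!length(bindings)) stop("no bindings given")
  rb_ids <- vapply(bindings, function(b) {
    if (length(b) != 2) stop("each binding must be a (predicate, object) pair")
    pred <- get_token(net, b[[1]])
    obj <- get_token(net, b[[2]])
    if (pred$layer != "PO" || pred$kind != "predicate") {
      stop("first element of a binding must be a predicate PO")
    }
    if (obj$layer != "PO" || obj$kind != "object") {
      stop("second element of a binding must be an object PO")
    }
    w <- c(1, 1)
    names(w) <- as.character(c(pred$id, obj$id))
    add_token(net, "RB", NA_character_, w, analog,
              meta = list(pred = pred$id, obj = obj$id))
  }, integer(1))
  if (length(rb_ids) == 1) return(rb_ids)
  w <- rep(1, length(rb_ids))
  names(w) <- as.character(rb_ids)
  add_token(net, "P", NA_character_, w, analog, meta = list(rbs = rb_ids))
}

analog_tokens <- function(net, analog, layer = NULL, kind = NULL) {
  ids <- net$analogs[[analog]]$tokens
  if (is.null(layer) && is.null(kind)) return(ids)
  keep <- vapply(ids, function(i) {
    tok <- net$tokens[[i]]
    (is.null(layer) || tok$layer %in% layer) &&
      (is.null(kind) || identical(tok$kind, kind))
  }, logical(1))
  ids[keep]
}

# --- serialization ----------------------------------------------------------

#' Serialize a network to a JSON checkpoint
#'
#' The schema is versioned and human-inspectable: a header with the pool
#' size and inhibition level, one record per analog, and one record per
#' token with its full downward edge list.  Weights are written at full
#' precision so that a round trip is bit-exact.
#'
#' @param net a [dora_network()].
#' @return A length-1 character JSON string.
#' @seealso [deserialize_network()]
#' @export
serialize_network <- function(net) {
  toks <- lapply(net$tokens[!vapply(net$tokens, is.null, logical(1))],
                 function(t) {
    list(id = t$id, layer = t$layer, kind = t$kind, analog = t$analog,
         edges = as.list(t$down), meta = t$meta)
  })
  obj <- list(
    format = "doralisa-network",
    version = 1L,
    pool_size = net$pool_size,
    inhibition = net$inhibition,
    next_id = net$next_id,
    analogs = lapply(net$analogs, function(a) a[c("id", "role")]),
    tokens = toks
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                null = "null"))
}

#' Rebuild a network from a JSON checkpoint
#'
#' The layering invariant is re-validated edge by edge; a blob whose edges
#' skip a layer (for instance an RB connected directly to a semantic unit)
#' is rejected.
#'
#' @param blob JSON string produced by [serialize_network()].
#' @return A [dora_network()].
#' @export
deserialize_network <- function(blob) {
  obj <- tryCatch(jsonlite::fromJSON(blob, simplifyVector = FALSE),
                  error = function(e) stop("malformed network blob: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "doralisa-network") ||
      !identical(as.integer(obj$version), 1L)) {
    stop("malformed network blob: missing or unsupported format/version")
  }
  net <- dora_network(pool_size = obj$pool_size, inhibition = obj$inhibition)
  for (a in obj$analogs) {
    aid <- add_analog(net, a$role)
    if (aid != a$id) stop("malformed network blob: analog ids not contiguous")
  }
  toks <- obj$tokens
  if (length(toks)) {
    ord <- order(vapply(toks, function(t) as.integer(t$id), integer(1)))
    toks <- toks[ord]
  }
  for (t in toks) {
    down <- unlist(t$edges)
    if (is.null(down)) down <- numeric(0)
    storage.mode(down) <- "double"
    meta <- if (is.null(t$meta)) list() else t$meta
    for (fld in c("pred", "obj", "rbs")) {
      if (!is.null(meta[[fld]])) meta[[fld]] <- as.integer(unlist(meta[[fld]]))
    }
    kind <- if (is.null(t$kind)) NA_character_ else t$kind
    net$next_id <- as.integer(t$id)  # preserve original ids
    id <- add_token(net, t$layer, kind, down, as.integer(t$analog), meta)
    if (id != as.integer(t$id)) {
      stop("malformed network blob: token ids not consistent")
    }
  }
  net$next_id <- as.integer(obj$next_id)
  net
}
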