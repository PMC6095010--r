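# Activation flow, asynchronous binding, and the inhibition-controlled
# competitions.  All competition sharpness is governed by a single
# temperature tau(lambda): high lateral inhibition means a cold, nearly
# winner-take-all competition, low inhibition a hot, nearly random one.

#' Competition temperature as a function of lateral inhibition
#'
#' \eqn{\tau(\lambda) = (1 - \lambda) + \epsilon}.  Strictly decreasing in
#' \eqn{\lambda}; the small \eqn{\epsilon} keeps selection finite at
#' \eqn{\lambda = 1}.
#'
#' @param lambda lateral inhibition in (0, 1].
#' @param epsilon temperature floor.
#' @return Numeric temperature.
#' @export
tau_lambda <- function(lambda, epsilon = 0.01) {
  (1 - lambda) + epsilon
}

softmax_probs <- function(score, tau) {
  z <- (score - max(score)) / tau
  p <- exp(z)
  p / sum(p)
}

#' Competitive selection of a driver proposition for working memory
#'
#' Propositions in the driver compete to enter working memory; the
#' competition is a softmax over support scores with temperature
#' \eqn{\tau(\lambda)}.  As \eqn{\lambda \to 1} selection approaches the
#' argmax (winner-take-all); as \eqn{\lambda \to 0} it approaches a random
#' draw.  Callers model firing recency by decaying the support of items
#' that have already fired (see `recency_decay` in [dora_config()]).
#'
#' @param support named numeric vector of support scores (one per
#'   candidate proposition or role-binding).
#' @param lambda lateral inhibition in (0, 1].
#' @return The name of the selected candidate.
#' @examples
#' set.seed(1)
#' select_for_wm(c(a = 2, b = 1), lambda = 0.999)  # "a" almost surely
#' @export
select_for_wm <- function(support, lambda) {
  if (!length(support)) stop("empty driver: nothing to select")
  if (is.null(names(support))) stop("support scores must be named")
  if (length(support) == 1) return(names(support))
  p <- softmax_probs(support, tau_lambda(lambda))
  names(support)[sample.int(length(support), 1L, prob = p)]
}

#' Firing schedule of a proposition (asynchronous role-filler binding)
#'
#' Binding information is carried by firing order: within each role-filler
#' pair the role PO fires directly before its filler PO, and distinct pairs
#' occupy disjoint consecutive slots.  For `contains(house, square)` the
#' schedule is outside, house, inside, square.
#'
#' @param net a [dora_network()].
#' @param prop_id id of a P unit or of a lone RB unit.
#' @return A list of slots, each a list with fields `po` (the firing PO
#'   id), `po_role` (`"role"` or `"filler"`), `rb` (the pair's RB id) and
#'   `p` (the parent P id or `NA`).
#' @export
fire_sequence <- function(net, prop_id) {
  top <- get_token(net, prop_id)
  if (top$layer == "P") {
    rbs <- as.integer(names(top$down))
    p_id <- top$id
  } else if (top$layer == "RB") {
    rbs <- top$id
    p_id <- NA_integer_
  } else {
    stop("fire_sequence expects a P or RB unit")
  }
  slots <- list()
  for (rb in rbs) {
    tok <- get_token(net, rb)
    if (tok$layer != "RB") stop("malformed proposition: child is not an RB")
    slots[[length(slots) + 1L]] <-
      list(po = tok$meta$pred, po_role = "role", rb = rb, p = p_id)
    slots[[length(slots) + 1L]] <-
      list(po = tok$meta$obj, po_role = "filler", rb = rb, p = p_id)
  }
  slots
}

#' Divisive competition among recipient units
#'
#' Raw inputs are passed through a divisive normalisation whose exponent
#' grows with lateral inhibition:
#' \deqn{a_i = in_i^{1/\tau(\lambda)} / \sum_j in_j^{1/\tau(\lambda)}.}
#' At high \eqn{\lambda} the strongest input takes (almost) all activation;
#' at low \eqn{\lambda} activation is shared.
#'
#' @param input numeric vector of non-negative raw inputs.
#' @param lambda lateral inhibition in (0, 1].
#' @return Numeric vector of activations summing to 1 (all zero when no
#'   unit receives input).
#' @export
divisive_competition <- function(input, lambda) {
  input <- pmax(input, 0)
  if (!any(input > 0)) return(input * 0)
  z <- (input / max(input))^(1 / tau_lambda(lambda))
  z / sum(z)
}

#' Recipient response to a firing semantic pattern
#'
#' The raw input to each recipient PO is the sum of shared-semantic
#' weights between the firing pattern and the unit; units then compete by
#' [divisive_competition()].  Units above the winner threshold (0.5 by
#' default) count as responding.
#'
#' @param net a [dora_network()].
#' @param footprint named numeric vector: the semantic pattern imposed by
#'   the firing driver unit (names are semantic ids).
#' @param recipient analog id of the recipient bank.
#' @param lambda lateral inhibition in (0, 1].
#' @return Named numeric vector of activations over the recipient's PO
#'   units (empty for an empty recipient).
#' @export
recipient_response <- function(net, footprint, recipient, lambda) {
  pos <- analog_tokens(net, recipient, layer = "PO")
  if (!length(pos)) return(stats::setNames(numeric(0), character(0)))
  input <- vapply(pos, function(i) sem_dot(footprint, net$tokens[[i]]$down),
                  numeric(1))
  act <- divisive_competition(input, lambda)
  stats::setNames(act, as.character(pos))
}
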