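#' Default engine configuration
#'
#' Collects every free constant of the simulator in one place.  The values
#' below define the model instance used throughout the package: they were
#' fixed once, against the pooled solution-type table, and are not intended
#' to be tuned per run.  Individual entries can still be overridden for
#' exploratory work via the `...` arguments.
#'
#' @param ... named overrides for individual entries.
#'
#' @return A named list of class `dora_config`.
#'
#' @details
#' The entries, with units and roles:
#' \describe{
#'   \item{gamma}{Hebbian learning rate in (0,1] for newly recruited
#'     predicate units; one saturating pass per comparison.}
#'   \item{eta}{learning rate for mapping-connection updates.}
#'   \item{n_passes}{full driver cycles run while mapping the A:C pair of an
#'     analogy problem.}
#'   \item{epsilon_tau}{floor added to the competition temperature
#'     \eqn{\tau(\lambda) = (1-\lambda)+\epsilon} so selection stays finite
#'     at \eqn{\lambda = 1}.}
#'   \item{winner_threshold}{normalised activation a recipient unit must
#'     reach to count as responding (and so to block recruitment of a new
#'     unit during self-supervised inference).}
#'   \item{recency_decay}{working-memory support is multiplied by this each
#'     time a proposition fires, so fresh propositions out-compete
#'     recently fired ones.}
#'   \item{items_per_trial}{range of LTM items co-inspected per learning
#'     trial.}
#'   \item{checkpoint_every}{learning trials between stored checkpoints.}
#'   \item{uniform_phase}{number of initial learning trials during which
#'     comparison items are drawn uniformly from the object pool.}
#'   \item{mix_relevant}{after `uniform_phase`, probability that a sampled
#'     item is drawn from the relevant learned predicates instead of the
#'     objects.}
#'   \item{support_gain}{scaling of the pairwise-similarity supports in the
#'     working-memory comparison competition; with \eqn{\tau(\lambda)} it
#'     sets how reliably well-matched items are compared rather than an
#'     arbitrary pair.}
#'   \item{relevance_threshold}{connection weight to a role's defining
#'     semantics above which a predicate counts as relevant to that role.}
#'   \item{sharpness_floor}{the comparison sharpening exponent used during
#'     learning is \eqn{1 / (\tau(\lambda) + \mathrm{floor})}: strong
#'     inhibition suppresses unshared semantics during comparison, weak
#'     inhibition lets them stay active and be learned into the new
#'     predicate.}
#'   \item{refine_decay}{per-refinement decay of connections to weakly
#'     co-active semantics when a learned predicate is compared again;
#'     with the co-activation sharpening this makes refinement both
#'     strengthen relevant connections and shed accidental ones.}
#'   \item{noise_scale, noise_power}{the uniform noise floor added to
#'     recipient inputs during mapping/inference has range
#'     `noise_scale * tau(lambda)^noise_power`: weak inhibition means a
#'     noisy, leaky competition in which many units respond to any firing
#'     pattern, and the chaos falls off steeply as inhibition rises.}
#'   \item{struct_support}{weight of role-slot to filler-slot structural
#'     support (a filler candidate inherits the activation its role-binding
#'     earned in the preceding slot).}
#'   \item{map_feed}{weight with which existing mapping connections feed
#'     recipient inputs.}
#'   \item{p_support}{weight of top-down support from an active proposition
#'     unit to role candidates beneath it.}
#'   \item{candidate_min_weight}{minimum connection weight to both defining
#'     semantics of a role for a learned predicate to be retrievable as a
#'     representation of that role.}
#'   \item{retrieval_gain}{scaling of predicate quality in the LTM
#'     retrieval competition; together with \eqn{\tau(\lambda)} it sets how
#'     reliably an individual retrieves its cleanest representation of a
#'     role.}
#'   \item{recruit_sem_weight}{connection weight with which a newly inferred
#'     (blank) object inherits the semantics of the driver object it
#'     mirrors.}
#'   \item{min_map_weight}{mapping weight below which a unit counts as
#'     unmapped when winners are extracted.}
#'   \item{prune_weight}{learned connection weights below this are dropped
#'     (weights are stored sparsely).}
#'   \item{lambda_clip}{admissible range for sampled inhibition values.}
#' }
#'
#' @examples
#' cfg <- dora_config(gamma = 0.5)
#' cfg$gamma
#' @export
dora_config <- function(...) {
  cfg <- list(
    gamma = 0.15,
    eta = 0.9,
    n_passes = 3L,
    epsilon_tau = 0.01,
    winner_threshold = 0.5,
    recency_decay = 0.5,
    items_per_trial = c(2L, 6L),
    checkpoint_every = 100L,
    uniform_phase = 100L,
    mix_relevant = 0.5,
    support_gain = 1,
    relevance_threshold = 0.9,
    sharpness_floor = 0.1,
    refine_decay = 0.85,
    noise_scale = 6.0,
    noise_power = 2.0,
    struct_support = 1.0,
    map_feed = 1.0,
    p_support = 0.5,
    candidate_min_weight = 0.25,
    retrieval_gain = 3,
    recruit_sem_weight = 0.5,
    min_map_weight = 0.1,
    prune_weight = 0.05,
    lambda_clip = c(0.05, 1.0)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown configuration entries: ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$gamma > 0, cfg$gamma <= 1, cfg$eta > 0,
            cfg$items_per_trial[1] >= 2, cfg$items_per_trial[2] <= 6)
  class(cfg) <- "dora_config"
  cfg
}
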