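---
title: "How doralisa learns relations and solves analogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How doralisa learns relations and solves analogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doralisa)
```

`doralisa` simulates how structured relational knowledge can be discovered
from unstructured perceptual input, and how the same representations then
support — or fail to support — analogical reasoning.  A single parameter,
top-down lateral inhibition $\lambda \in (0, 1]$, controls every
competitive process in the simulator and stands in for an individual's
inhibitory control.  Holding $\lambda$ fixed within a simulated individual
and varying it across individuals reproduces the three learning
trajectories reported in longitudinal work on children's geometric
analogies — non-analogical throughout, transitional, and analogical
throughout — together with their characteristic error profiles.

This vignette is the package's account of the model: the representational
format, the dynamics, the learning and mapping algorithms, the synthetic
stimulus generator, the free parameters and how they were fixed, and the
limits of what the simulations show.

## Representations

Knowledge lives in a strictly layered network over a shared pool of 1000
*semantic* units (ids `0 ... 999`).  Semantic units carry no intrinsic
meaning; they are stand-ins for perceptual invariants the system can
detect reliably.  Above them sit three layers of localist token units:

* **PO units** code single predicates (relational roles) or objects, via
  weighted connections to semantic units;
* **RB units** conjunctively bind exactly one predicate PO to one object
  PO (a role–filler pair);
* **P units** link sets of RBs into whole multi-place propositions.

`contains(house, square)` is therefore a P unit over two RBs, one binding
the role *outside* to *house* and one binding *inside* to *square*.  No
connection may skip a layer; the invariant is checked on every mutation
and on deserialization, so a checkpoint file with, say, an RB connected
directly to a semantic unit is rejected.  All connection weights live in
$[0, 1]$ and are stored sparsely.  Networks serialize to a versioned,
human-readable JSON schema (`serialize_network()`), with weights written
at 17 significant digits so round trips are bit-exact.

Role–filler binding is carried by *time*, not by dedicated binding units:
when a proposition fires, its role and filler POs occupy alternating,
disjoint slots, each role directly before its filler
(`fire_sequence()`).  This is what keeps *inside* bound to *square*
rather than to *house* while using the same units that would code those
concepts in any other proposition.

## One temperature for every competition

All competitive processes share the temperature

$$\tau(\lambda) = (1 - \lambda) + 0.01,$$

with the small floor keeping selection finite at $\lambda = 1$.  Three
competitions matter:

1. **Entry into working memory** (`select_for_wm()`): candidates are
   sampled from a softmax over support scores at temperature
   $\tau(\lambda)$.  At $\lambda \to 1$ this is argmax; at low $\lambda$
   it approaches a random draw.  Support decays by one half each time a
   proposition fires, so under strong inhibition the driver cycles
   systematically through its propositions, while under weak inhibition
   firing order becomes erratic.
2. **Recipient response** (`recipient_response()`): units receiving raw
   input $in_i$ (the sum of shared-semantic weights with the firing
   pattern) divide activation as
   $a_i = in_i^{1/\tau} / \sum_j in_j^{1/\tau}$ — nearly winner-take-all
   under strong inhibition, widely shared under weak inhibition.  A unit
   counts as *responding* when its activation reaches 0.5.
3. **Retrieval from long-term memory** (at test encoding): the predicate
   used to represent a transformation role is drawn by a softmax over
   candidate qualities, again at $\tau(\lambda)$, scaled by
   `retrieval_gain`.  Weak inhibition retrieves relationally dirtier
   representations even when cleaner ones exist.

Inside the mapping and inference engine the recipient competition
additionally receives a uniform noise floor with range
`noise_scale` $\cdot \tau(\lambda)^{\texttt{noise\_power}}$, plus one
"leak" competitor drawn from the same distribution.  This is the
package's concrete rendering of low-inhibition chaos — many units
responding weakly to any firing pattern — and it falls off steeply as
inhibition rises.  The exported `recipient_response()` stays the bare
divisive formula; the noise floor exists only where banks interact.

## Learning structured representations by comparison

Learning starts from 100 objects coded as flat feature vectors: each
object carries the defining semantics of two to four of the five
geometric transformations (adding an element, changing size, halving,
doubling, changing containment — the binary one contributing exactly one
of its two roles, chosen at random) plus four idiosyncratic features.

Each of the 800 (or 1000) learning trials samples two to six items from
memory, lets pairs compete for working memory with supports equal to
their normalised semantic overlap, and compares the winning pair:

* the co-activation of each semantic unit is computed as in
  `coactive_semantics()` — shared features roughly twice as active as
  unshared ones — then raised to a sharpening exponent
  $1 / (\tau(\lambda) + 0.1)$.  Strong inhibition suppresses the
  weakly active (unshared) semantics almost completely; weak inhibition
  lets them stay active and be learned;
* a new predicate PO is recruited with one saturating Hebbian pass,
  $w(s) = \min(1, \gamma\,a(s))$ with $\gamma = 0.15$
  (`predicate_from_comparison()`);
* when a learned predicate takes part in the comparison, the pass
  *accumulates* onto it: co-active semantics gain $\gamma$ per comparison
  (so a connection seen in $k$ comparisons follows
  $\min(1, k\gamma)$), while weakly co-active connections decay by
  `refine_decay` of their distance from full activation.  Refinement
  therefore both strengthens and sharpens;
* old tokens are never modified or deleted — refinement recruits new
  units and the archive grows append-only, which makes a checkpoint fully
  described by a count of predicates.

When a compared pair of objects carries complementary containment roles,
the two freshly recruited role–filler bindings co-fire and a P unit is
recruited over them (`form_relation()`), yielding a rudimentary
multi-place `contains` structure.

Training is deliberately unstructured: items are sampled uniformly from
everything in memory (objects and learned predicates alike), except that
after the first 100 trials half the draws come from *relevant* predicates
— those connected above 0.9 to a role's defining semantics.  Nothing
tells the learner which comparisons are worthwhile; under strong
inhibition the overlap-driven competition finds them anyway, which is
exactly why high-inhibition individuals learn faster and cleaner.

**Representation quality.**  A predicate's quality for a role is the mean
of its connection weights to the role's two defining semantics divided by
the mean of all its other nonzero connection weights plus one — bounded
in $[0, 1]$, with the +1 guaranteeing the bound.  The per-checkpoint
summary reported in `learn_relations()` is the *expected retrieved
quality*: for each of the six roles, the softmax-weighted mean quality of
the candidate predicates the individual could retrieve for that role at
its own inhibition level, averaged over roles.  This measures the
relational knowledge actually available for reasoning; the cumulative
archive (which keeps every early, junky predicate forever) is available
per predicate in `quality_by_role`.

```{r learning, fig.width = 6, fig.height = 4}
set.seed(7)
fit <- learn_relations(generate_world(), lambda = 0.8, n_trials = 400)
fit$checkpoints
```

## Mapping and self-supervised inference

An analogy problem is encoded with the A and B terms in the *driver* bank
and the C term in the *recipient*; the A–C correspondence is never given
and must be discovered.  Each term's objects are POs with four
idiosyncratic semantics, bound to the learned transformation predicates
retrieved from LTM; a role for which no predicate qualifies (connection
above `candidate_min_weight` to both defining semantics) is simply left
unencoded — the term then carries object features only and that
transformation can never be inferred.

`map_analogs()` runs three full driver cycles over the A-term
propositions.  Each firing walks the asynchronous schedule; recipient
predicates respond to the semantic pattern, recipient objects respond to
structural support (the activation their role–binding earned in the
directly preceding role slot) plus mapping-connection feedback; and
mapping connections between co-active units are updated Hebbianly with
subtractive normalisation against the strongest competing hypothesis in
the same row or column ($\Delta m = \eta(a_d a_r - a_d \max m_{other})$,
$\eta = 0.9$, clipped to $[0,1]$).  Structural support is what lets
featurally disjoint fillers map through their shared roles.  Winner maps
are extracted greedily, one-to-one per layer.

`infer_missing()` then fires the driver propositions left without a
mapping winner — the B term.  Each firing unit activates recipient
candidates through its semantics and its mapping connections (units
already claimed by other driver units are suppressed); if no unit
responds above 0.5, a new recipient unit is recruited mirroring the
driver unit — predicates copy their semantics, objects are new blank POs
inheriting the driver object's semantics at half weight — and RB/P units
are recruited over the images.  The recruited-or-matched propositions are
the generated D term.  If no mapping formed at all, inference is refused
and the empty answer is scored as a failure.

A trial is classified (`classify_response()`) *analogical* when every
required transformation appears in D with the correct role-to-object
assignment, *incomplete* when at least one but not all do, and
*associative* when none does — including empty answers and bare copies of
C's objects.  Transformation instances of the same kind are
interchangeable: scoring matches the set of inferred propositions, so a
wholesale exchange of two identical containment instances is still
correct.

## The stimulus generator

`generate_battery()` draws A:B::C:D items at the study's difficulty mix:
30% hard (three transformations), 35% medium (two), 35% easy (one),
apportioned at finite $n$ by largest remainder (6/7/7 at $n = 20$), with
the stated unary/binary sub-mixes inside each class.  Unary
transformations apply a predicate to one object; the binary containment
transformation exchanges the container and contained objects between A
and B.  C instantiates the same transformations as A over fresh objects
with disjoint features, and the correct D is stored as a role structure
over C's objects.  Difficulty is descriptively summarised by
$0.5 \times \mathrm{elements} + 1 \times \mathrm{transformations}$, with
elements read as the number of objects in the A term.

What the generator deliberately does *not* emulate: drawn geometric
shapes (objects are anonymous feature bundles), featural lures shared
between A and C (off by default), item norming, or feedback to the
learner during testing.  Passing tests therefore show that the
*mechanism* produces the right performance structure on stimuli with the
study's statistics — not that it would survive the perceptual front-end
of real geometric drawings.

## The longitudinal protocol

`simulate_trajectories()` runs four groups through the full protocol.
For each simulated individual: draw $\lambda$ once from the group's
distribution ($N(0.4, 0.1)$, $N(0.6, 0.1)$ or $N(0.8, 0.1)$, clipped to
$[0.05, 1]$ — inhibition is treated as maturational and reused across
learning and all tests), learn from a fresh random world, then solve
eight phases of twenty freshly generated items.  The low-knowledge groups
train for 800 trials and use the checkpoint after $100t$ trials at phase
$t$; the high-knowledge group trains for 1000 trials and uses checkpoint
$100t + 200$, modelling children who enter the study with more advanced
relational knowledge.

```{r experiment, eval = FALSE}
ex <- simulate_trajectories(n_sims = 30, seed = 1)
print(ex)
plot(ex)
write_experiment_csv(ex, "results")
```

With 30 individuals per group this takes roughly four minutes on one CPU
(100 per group, as in the full study design, scales linearly).  The
package's tests and the bundled `scripts/acceptance.R` run at the
30-individual desk scale.

## Free parameters and calibration

The mechanisms above leave a handful of constants the source literature
does not pin down: the Hebbian rate $\gamma$, the refinement decay, the
sharpening floor, the mapping rate $\eta$, the number of mapping passes,
the relevance-mixing probability, the noise floor scale and power, the
structural-support weights, and the retrieval gain.  These were
calibrated **once**, against the pooled solution-type percentages of the
three trajectory groups (and the high-knowledge variant), on a held set
of seeds, and then frozen in `dora_config()`.  They are documented there
with units and roles; none is intended to be tuned per run.  The
behavioural orderings — quality increasing in $\lambda$, the three
trajectory shapes, associative errors decreasing in $\lambda$ and fading
within the transitional group — emerge from the frozen configuration
rather than being imposed.

Numerical choices worth knowing about:

* winner threshold 0.5 on normalised activations (unambiguous with two
  competitors);
* mapping winners require weight $\ge 0.1$; ties break by weight, then
  lowest driver id, then lowest recipient id;
* learned connections below 0.05 are pruned (sparse storage);
* degenerate inputs — empty recipients, all-zero competitions, batteries
  of size 1, checkpoints with zero predicates — all return well-defined
  empty results rather than errors; genuinely malformed structure
  (reversed bindings, layer-skipping edges, out-of-pool semantics)
  errors immediately.

## Known limitations

* The two-containment items are the model's hardest case: when mapping
  fails there it tends to fail for both instances at once, so the
  simulated transitional group produces somewhat more associative (and
  fewer incomplete) errors than the behavioural reference pattern.
* Within-individual improvement in the transitional group comes mostly
  from knowledge growth between checkpoints; the simulated rise over
  phases is shallower than the steepest individual children's curves.
* Mapping connections reset between trials; there is no learning during
  test phases, no schema induction, and no retrieval of whole analogs
  from LTM during testing.
* The model makes no claims about reaction times or about the biological
  implementation of inhibition.
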