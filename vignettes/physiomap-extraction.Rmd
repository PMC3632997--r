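---
title: "Extracting and interrogating process-participant graphs from biosimulation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and interrogating process-participant graphs from biosimulation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiomapr)
```

## The representation

A PhysioMap is a graph over two node populations. *Dynamical entities* are
the bearers of physical properties: a portion of blood contained in the
left ventricle, glucose in the cytosol. *Dynamical processes* come in two
kinds. A **flow** process moves a quantity of stuff — and the thermodynamic
energy attending it — from its *source* entities to its *sink* entities,
possibly enabled by *mediators*; blood flow between vascular compartments
and molar chemical flux through a reaction are the same structure in
different biophysical domains. A **modulation** process is the influence of
one property on another without significant energy flow — an enzyme or an
allosteric inhibitor acting on a reaction rate — and carries a polarity:
+1 (stimulation), −1 (inhibition) or 0 (direction unknown).

Model variables are linked to this vocabulary by *composite annotations*:
a physical-property term paired with the entity bearing it, the entity
optionally refined by structural relations (`part-of`, `contained-in`,
`connected-to`). The property terms come from a compact shipped registry
(`load_registry()`): a forest of force, amount and flow-rate properties
across fluid, chemical, electrical and diffusion domains, with `part-of`
style subsumption queried by `is_subclass_of()` and classification by
`classify_property()`. The registry mints local CURIEs (`opbx:`, `fmax:`,
`chebix:`) and leaves an `external_iri` slot for reconciliation with the
published ontologies it abbreviates; bearer terms outside the registry are
treated as opaque identifiers, since reasoning over anatomy or chemical
ontologies is out of scope.

Two design choices here deserve a note. *Entity identity ignores the
property*: pressure and volume observed on the same portion of blood
describe one entity, so identity is the bearer chain (or, for unmapped
species, a case-normalized free label). *Annotation equivalence is exact* —
no subsumption is consulted when comparing annotations, because silently
unifying "blood in aorta" with a broader vascular class would fabricate
identity the model never asserted; a subsumption-aware mode could be added
behind the same predicate without changing any caller.

## From model code to a map

Two ingestion routes produce one uniform in-memory model: an SBML reader
(species, compartments, parameters, reactions with kinetic-law MathML,
rate/assignment rules, MIRIAM-style annotation URIs, SBO modifier terms)
and a small line-oriented equation-model format (`var`/`eq`/`init`
statements with inline annotations, `x'` marking time derivatives) standing
in for general equation-based languages. Expressions are restricted to
`+ - * / ^`, unary minus, numbers and variable references; SBML constructs
outside that language (e.g. piecewise math) are kept as dependency-only
equations with a warning, and any sign query against them answers
*indeterminate* rather than guessing.

**Explicit tags.** When reaction records exist, `infer_from_reactions()`
maps each reaction to a chemical flow process: reactants become source
participants and products sink participants with their stoichiometries;
each modifier becomes a modulation process targeting the flow, polarity
taken from inhibitor-family (−1) or stimulator-family (+1) SBO terms and 0
otherwise. A reaction with an empty side gets an implicit *environment*
entity and an `unresolved` flag — the unmodeled exterior of a boundary
flux.

**Dependency inference.** Without tags, `infer_from_dependencies()` works
from the variable dependency graph (edge `u -> v` iff `u` appears in the
equation defining `v`, including derivative equations into their state).
For every flow-rate-annotated variable:

1. *Upstream*: breadth-first traversal backwards, stopping on each branch
   at the first force or amount variable of the flow's own domain. The
   traversal passes through unannotated, other-role and wrong-domain
   variables (wrong-domain force/amount encounters are recorded but do not
   stop the branch), with a 10-hop cap and a per-direction visited set so
   cycles terminate.
2. *Downstream*: the same traversal forwards, finding the force/amount
   variables that depend on the flow.
3. Each piece of evidence carries a sign: the product of numerically
   estimated partial-derivative signs along its path (central differences
   at the model's nominal values, relative step 1e-6, a zero band at 1e-12,
   and a cross-check at step 1e-4 — disagreement between the two steps, or
   an unevaluable expression, yields *indeterminate*). Missing nominal
   values default to 1.0, a positive point that avoids spurious zeros in
   monotone rate laws.
4. Role assignment follows the driver orientation of resistive laws:
   upstream dependence +1 → source, upstream −1 → sink, downstream +1 →
   sink, downstream −1 → source. Duplicate (entity, role) pairs collapse;
   an entity assigned both source and sink by definite signs is demoted to
   mediator with a `role-conflict` flag rather than silently dropped.

One disambiguation is ours: a same-domain **amount** variable found only
upstream, with no downstream coupling of its entity back to the flow and
not itself a constant boundary input, is emitted as a *modulation* with the
dependence sign as polarity instead of a participant. This is what makes an
enzyme appearing as a factor in a mass-action rate law come out as a
stimulating modulation — matching what explicit tags say about the same
model — while a pressure driving a resistive flow (a force, or an amount
whose entity the flow depletes or fills) remains a participant. The
flip side is a genuine limitation: a constant supply pool feeding a tagged
reaction is mathematically indistinguishable from a constant activator, and
the dependency path will report it as a modulation where the tags say
source. Untagged semantics can simply be obscured; the per-flow evidence is
therefore attached to the returned map (`attr(map, "evidence")`) instead of
being discarded.

Entities are minted from the bearer of each evidence variable's annotation
and merged by identity, process ids are derived from flow-variable names,
and all orderings are lexicographic, so the same model always yields
byte-identical PhysioMap XML.

## Qualitative interrogation

`to_signed_graph()` turns a map into a signed influence graph: source and
mediator entities feed their flow with +1 edges, flows feed sinks with +1
edges, regulators feed their modulation node with +1 and the modulation
feeds its target with its polarity (0 kept as a 0-sign edge). The graph is
layered — no edge joins two entities; the only process-process edges are
modulation → target. Source *depletion* edges (flow → source, −1) are off
by default: the default reading of a perturbation is the downstream
increment it causes, and depletion loops (every reaction depletes its
substrate) otherwise dominate loop listings; `include_depletion = TRUE`
turns them on.

`propagate()` computes a fixed point over the lattice
`unset < up|down < ambiguous`: a node's state is the join of its initial
perturbation and edge transmissions, where +1 preserves, −1 flips, and a
0-sign edge transmits `ambiguous` from any perturbed source — an unlabeled
modulator may act either way, and silence would understate that. `clamp`
models a quantity held constant experimentally: it absorbs influence and
transmits nothing. The update is monotone on a finite lattice, so the
sweep loop terminates; each productive sweep raises at least one node and a
node can rise at most twice, bounding sweeps by twice the node count. A
node inside a feedback loop reached with conflicting signs reads
`ambiguous` — the conservative qualitative-reasoning answer — and loops are
instead reported structurally by `detect_feedback_loops()`, which
enumerates elementary cycles (canonical rotation, smallest id first, length
cap 20) and classifies polarity by the parity of −1 edges, with any 0-sign
edge making the loop indeterminate. `find_paths()` enumerates simple
signed A-to-B paths depth-first in lexicographic order; paths do not
revisit nodes, and cycles back to the start are the loop detector's job,
not the path tracer's.

## Merging

`merge_physiomaps()` unifies entities by annotation equivalence and
processes by their *full* signature — kind, domain and the complete
participant set with roles and stoichiometries (for modulations: regulator,
target and polarity). Partial overlap is deliberately a *conflict*, not a
match: two flows sharing participants but disagreeing in polarity or
stoichiometry are both retained under disambiguated ids and reported,
because guessing which variant is right is curation, not bookkeeping.
Matching is per-multiset (each process absorbs at most one counterpart), so
merging is commutative up to isomorphism and merging a map with itself or
with the empty map is neutral. Node *ids* in the result do depend on
argument order; semantic content does not.

## The synthetic models and what they show

Three generators provide the reference inputs; each attaches its declared
construction counts as an attribute at generation time, and tests compare
against those declarations rather than repeating constants.

* `make_glycolysis_toy()` — a six-metabolite, five-reaction irreversible
  mass-action chain (glucose through pyruvate) with a stimulating
  hexokinase pool on the first reaction (`k1 * glucose * HK`) and an
  inhibiting citrate pool on the third (`k3 * F6P / citrate`), all species
  carrying cytosolic chemical annotations. It mirrors the *topology* of a
  curated glycolysis fragment — chain plus tagged modulators — not any
  published parameterization; rate constants are order-one values chosen
  for well-conditioned short-time dynamics.
* `make_cv_circuit(n)` — a closed ring of `n` blood compartments with
  linear compliances and resistive inter-compartment flows, compartments
  named so that `F_LV_aorta` exists. Unit compliances and resistances and
  order-one volumes (the first compartment 50% overfilled to drive flow)
  keep the system linear and conservation exactly checkable: on the closed
  two-compartment ring total volume is conserved to machine precision by
  construction, which the integrator test asserts at 1e-6.
* `make_random_network(n_species, n_reactions, p_modifier, seed, acyclic)`
  — seeded unimolecular mass-action conversions (`k * reactant`, rate
  constants and initial values uniform on [0.5, 2]); with probability
  `p_modifier` a reaction is instead a modulated boundary-synthesis flux
  (`k * M` or `k / M`, definite random polarity, modifier drawn from
  already-produced species). In acyclic mode indices are ordered so the
  derived influence graph is a DAG.

The ODE machinery behind the numeric cross-check is deliberately plain:
fixed-step classical Runge-Kutta on an equally spaced grid (via deSolve's
`rk4`), default step `t_end / 200` — small against the order-one rate
constants above — with algebraic assignments re-evaluated in topological
order each step. `numeric_sign_oracle()` perturbs one initial value by a
relative `epsilon` and reports response signs at a probe time with an
absolute dead-band of 1e-9. Checks that compare propagation against this
oracle use 100 six-species networks, a 20% perturbation and probe time 0.5:
a response attenuates roughly by another factor of (rate × time) per chain
step, and these sizes keep even the deepest reachable node's response
comfortably above the dead-band while leaving unreachable nodes at exactly
zero. The glycolysis end-to-end example uses a 5% perturbation for the same
reason — at 0.1% the pyruvate response after five stages sits below the
dead-band.

What passing these checks shows — and does not. The generators produce
unimolecular networks, so qualitative propagation and the numeric response
agree exactly along material paths. Real kinetic laws are often
multimolecular: a perturbation then *depletes co-substrates* of downstream
reactions, an effect the default (depletion-off) signed graph does not
carry. The machinery is exercised on the structure the generators emulate;
on models with strong co-substrate coupling the depletion-on graph is the
right instrument, and ambiguity will be more common.

## Numerical and degenerate-input choices

Indeterminate dependence signs (sign flips across step sizes, division by
zero at the nominal point, unsupported math) never orient a participant;
they become polarity-0 modulations, which propagate as `ambiguous`.
A flow with no definite evidence still yields a process — flagged
`unresolved`, with environment entities on the empty sides — so boundary
fluxes remain visible rather than vanishing. Empty models, models without
flow annotations, and empty maps are all legal and produce empty results
with warnings where the outcome is likely unintended. Serialization
canonicalizes everything (sorted ids, fixed attribute order, LF, UTF-8) so
write → read → write is byte-identical, which the tests assert over random
maps.

## Limitations

* Capacitive and transducer processes (energy storage and cross-domain
  conversion) are not inferred; only flow and modulation processes are.
* Temporal relations between processes (*precedes*, part-whole over
  processes) are not represented.
* The dependency path cannot distinguish a constant supply pool from a
  constant stimulator (see above), and reversible reactions are kept as a
  single flow process — a negative net rate is a tracing concern, not a
  structural one.
* Composite-annotation matching is exact; models annotated against
  different granularities of the same ontology will not unify without
  harmonizing their annotations first.
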