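---
title: "Modelling clinical information flow in emergency psychiatric care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinical information flow in emergency psychiatric care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carepath)
```

## The modelling problem

When a patient presents to an emergency department (ED) at risk of suicide
or self-harm, the quality of their care depends on how reliably clinical
information moves between triage staff, treating doctors, psychiatric
liaison staff and the information systems they read and write. carepath
models that flow from a purely observational event log: each row records
one interaction — the agents present, the systems accessed, the time, and
any resulting action such as a referral or discharge. Nothing about the
clinical *content* of an interaction is used; the models see only timing,
participants and actions. That is both the method's strength (it is
minimally invasive and blind to clinical detail) and its central
limitation: an edge says that a channel was used at least once, not how
much information crossed it.

Three analyses are layered on the log:

1. **Structure.** An undirected clinical interaction network with one node
   per agent or information system and an unweighted edge wherever a pair
   interacted at least once. Centrality (degree, closeness, betweenness)
   ranks agents by their importance for information flow; greedy modularity
   detection asks whether interaction patterns alone recover the clinical
   team structure.
2. **Vulnerability.** A degree-preserving null model asks whether a node's
   betweenness is higher than chance would produce in similar networks;
   node removal quantifies the efficiency cost of losing an agent; greedy
   edge addition searches for the cheapest way to repair that cost.
3. **Decision points.** A dynamic network state is grown along each
   trajectory and a Bernoulli naive Bayes classifier is trained to locate
   the interaction that precipitates referral to Emergency Psychiatry,
   with permutation importance attributing the prediction to specific
   nodes and edges.

## The interaction network and its policy

Records list two or more parties per interaction, while the network is
defined on pairs. Each record is expanded to the clique over its agents
plus all agent–system pairs: an interaction among the listed parties is
taken to imply pairwise interaction. This is a deliberate design choice —
the alternative (a hyperedge or star expansion) would either need an
arbitrary focal agent or lose the agent–agent structure entirely, and the
clique reading matches the definition of an edge as "at least one
interaction between the pair".

Not every pair is admissible. The operational policy of a hospital implies
**forbidden edges**, applied both when building networks and inside the
null model: (a) two information systems never interact directly; (b) a
system connects only to clinical staff (a patient never directly accesses
their own file); (c) psychiatry-restricted systems (PSOLIS, the psychiatry
online record, and EDYHO, the psychiatry handover document) connect only to
Emergency Psychiatry staff. Edges are unweighted and undirected;
interaction frequencies are kept as node metadata for reporting but enter
no computation, because with a few hundred observed interactions the
frequency estimates would be far noisier than the edge set itself.

Patients observed only in the MHOA (the short-stay mental-health unit
adjacent to the ED) are excluded from ED statistics and the interaction
network, because the unit serves a different model of care; patients seen
in both settings keep all of their records.

### Centrality conventions

Degree and betweenness follow the standard definitions; betweenness counts
shortest-path multiplicities exactly (Brandes accumulation, via igraph) and
is normalized by `(n − 1)(n − 2)/2`, the number of unordered pairs that
could route through a node, so values lie in [0, 1]. Closeness is
`(n − 1)/Σ_j d_ij` on connected graphs. After node removal the graph can
disconnect, so closeness uses the Wasserman–Faust scaling — within-component
closeness times the fraction of other nodes reachable — keeping values
finite and comparable across removal scenarios; an isolated node scores 0.
Global efficiency averages `1/d_ij` over ordered pairs with unreachable
pairs contributing 0; it is 1 exactly on a complete graph and 0 on an
edgeless one, and is undefined (an error) below two nodes.

Community detection is agglomerative greedy modularity maximization.
Because merge order matters when gains tie, ties are broken
deterministically toward the lexicographically smallest community pair
(communities labelled by their alphabetically first member), merges stop
when no gain exceeds `1e-12`, and disconnected components are never merged.
Determinism matters more than squeezing out the last fraction of
modularity: the partition feeds figures and tests, and a tie-broken run
must reproduce.

## The null model

The shuffled ensemble uses a constrained connected double-edge swap: two
connected pairs (i, j) and (v, u) are drawn uniformly, and rewiring to
(i, v) and (j, u) is applied only when both new edges are absent,
non-forbidden, create no self-loop, and leave the graph connected.
Connectivity is checked per swap and the swap reverted on failure, rather
than batching checks, so every intermediate network in a shuffle sequence
is itself a valid sample. An *attempt* is counted whether or not it
succeeds; each ensemble member applies a fixed number of attempts (default
20,000) from its own RNG substream. One master seed draws per-shuffle child
seeds, so ensembles are reproducible bit for bit and members can be
regenerated independently. The default ensemble size is 1,000; the
packaged analyses and acceptance script use 100-shuffle ensembles, which
keep the full pipeline in seconds while the percentile statistic only needs
resolution around its 95th-percentile threshold.

The swap loop is implemented twice: a compiled (Rcpp) fast path and a
pure-R reference that consumes the identical RNG stream; the test suite
asserts bit-identical agreement, so the compiled engine is verified against
readable R code.

A node's betweenness percentile is computed against the null distribution
of *that node's own* betweenness across the ensemble (not pooled across
nodes — pooling would conflate a node's position with the overall
betweenness scale), with midpoint handling of exact ties to avoid flag
flips from floating-point equality; a node is flagged above the 95th
percentile.

### Removal and restoration

Node removal reports the percentage change in global efficiency and the
closeness change for every doctor. Greedy restoration removes the
compromised node and adds candidate edges one at a time, always the edge
with the largest efficiency gain. The default candidate set is every absent
doctor–doctor pair spanning the Emergency Medical and Emergency Psychiatry
teams — the repair the analysis is designed to evaluate is precisely
strengthened inter-team communication between doctors — and is overridable.
When gains tie (within `1e-12`), a single greedy order is no longer
canonical, so the complete set of step-wise optimal orderings is enumerated
over the lattice of candidate subsets (efficiencies are memoized per
subset, making the enumeration cheap even when every ordering ties) and the
tied candidates are reported as tie groups. Efficiency is non-decreasing
along every trace, and the final value is order-independent because the
final edge set is.

## The referral model

For each patient referred to Emergency Psychiatry, a cumulative network is
grown one interaction at a time up to and including the referral
interaction; the final state is the positive example and all earlier states
are negative, so every referred patient contributes exactly one positive.
States are vectorized as node indicators followed by upper-triangle edge
indicators in row-major order, aligned to the full network's node ordering.
The upper-triangle layout (rather than the full `n × n` matrix) is used
because the features of an undirected state are the `n(n−1)/2` unordered
pairs; a full-matrix layout would duplicate every edge feature.

Bernoulli naive Bayes with Laplace smoothing (`α = 1`, so conditional
probabilities are `(count + 1)/(n_class + 2)` and never degenerate) is a
deliberately simple classifier: binary inputs match the state vector
exactly, and with ~87 states against ~170 features anything more flexible
would memorize. Posteriors are computed in log space; an exact posterior
tie predicts "no referral", the conservative default. Evaluation uses
balanced accuracy, since positives are ~23% of states, over
patient-grouped 80:20 splits — grouping is essential because states within
a trajectory are strongly dependent, and splitting a patient across train
and test would leak the trajectory. Training splits oversample whole
minority-class state vectors with replacement to class balance; splits
whose test (or training) side lacks a class are rejected and redrawn
because balanced accuracy is undefined there, and the rejection count is
reported.

Permutation importance permutes each feature once per split, within the
test partition only (permuting training features would measure a different
quantity — sensitivity of fitting, not of prediction), and reports the mean
drop in balanced accuracy with empirical percentile 95% intervals over
splits. Negative importances are real and reported as-is. Because the
classifier is linear in the features on the log-posterior scale, a permuted
column shifts the decision margin by `(x_perm − x) · w_f`; importance is
computed by margin adjustment rather than re-scoring, which makes 1,000
splits × ~170 features run in seconds with results identical to naive
re-prediction. The package default is 10,000 splits; tests and the
acceptance script use 1,000, which stabilizes the mean importance ranking
while keeping the suite fast.

## The synthetic generator

No observational event log of this kind can be redistributed, so the
package ships a generator that plants the structure the analyses measure,
not clinical content:

- two clinical teams with realistic interaction patterns (triage, nursing
  observations, doctor assessments, bedside rounds, handover of
  ambulance/police escorts to treating staff, system access);
- a hub agent — the Psychiatric Liaison Nurse — through which cross-team
  information flow is routed with probability `hub_mediation_prob`
  (default 0.9, high because the planted structure under test is hub
  mediation; at 0 the teams communicate doctor-to-doctor directly);
- referral triggers: the referral action fires at the first occurrence of
  a planted signature (Registrar with the Patient File, or Consultant with
  the Patient, equally likely), and the generator withholds those
  signatures from earlier interactions so the referral point is
  identifiable from the state vector;
- information systems only ever listed alongside staff permitted to access
  them, so no record reduces to a forbidden pairing;
- exponential inter-interaction gaps (mean 20 minutes, chosen so the
  median trajectory time sits near 1.5 h under the default
  interaction-count distribution: counts on 2–12 with median 5).

Defaults emulate a cohort of 36 ED trajectories plus 7 MHOA-only
trajectories with 20 referrals. `study_scale_fixture()` additionally pins
per-trajectory interaction counts (summing to 213 ED + 59 MHOA = 272
records) and referral steps (summing to 87 pre-referral states) so that
pipeline bookkeeping can be verified end to end against exact numbers. The
fixture is labelled synthetic throughout: it reproduces sample sizes and
planted structure, not observed data.

What the generator does *not* emulate: clinical content, acuity, queueing
or shift structure, interaction durations, and the long tail of rare agent
types a real ED would show. Consequently, passing the planted-structure
tests demonstrates that the pipeline *recovers structure that is present*
— hub mediation, team modularity, trigger signatures — not that any
particular hospital exhibits that structure. Two further consequences are
worth noting. First, with an unweighted clique expansion the synthetic
medical team is internally dense, and modularity maximization may split it
into patient-facing and records-facing subgroups; the planted team
*boundary* is respected (no community mixes the two teams' staff, and the
psychiatry team stays whole with its restricted systems), which is the
property the tests assert. Second, per-trajectory staff-type medians land
on the 4–5 boundary rather than exactly 4, a consequence of drawing
secondary staff independently per interaction.

## Interval and counting conventions

Cohort "95% intervals" on per-trajectory statistics are empirical 2.5th to
97.5th percentiles of the per-patient values (quantile type 7), not
bootstrap intervals of the median: with 36 patients a bootstrap of the
median is lumpy, and the empirical band answers the more useful question —
the range in which most trajectories fall. The same percentile convention
is used for importance intervals. "Types of clinical staff" counts distinct
catalog names (two interactions with *the* Nurse count once; a Nurse and a
Triage Nurse count twice); counting roles instead would be coarser and is
a documented alternative, not the default. A patient's presentation mode is
read from their first record, later records must agree, and a combined
arrival such as "Ambulance+Police" is one categorical level. Timestamps are
parsed as `DD/MM/YYYY HH:MM` (24 h), timezone-naive, at minute precision;
trajectories are assumed not to span a date boundary alteration.

## Degenerate inputs

Single-record trajectories have trajectory time 0 (not an error). An empty
log builds an empty network with a warning. A referral action naming the
team already treating is ignored with a warning. Betweenness is identically
0 below three nodes; efficiency raises below two. A triangle admits no
double-edge swap (every proposal self-loops or duplicates), and zero
attempts return the input network unchanged. Fitting the classifier on
single-class data is an error directing the caller to oversample.

## Problem sizes

The shipped analyses run at: 100-shuffle ensembles of 20,000 attempts each
(compiled swap loop; ~1–2 s), 1,000 grouped resampling splits for the
referral model (~4 s via margin adjustment), oracle comparisons on 200
random graphs of at most 8 nodes, and exhaustive-ordering restoration
oracles for up to 4 candidate edges. These sizes were chosen so the entire
verification pipeline runs in well under a minute while leaving every
statistic's resolution comfortably finer than the effects it measures.

## Known limitations

- Edges are binary; a channel used once and a channel used hourly are
  indistinguishable. Weighted or duration-aware variants are out of scope.
- The interaction network pools all patients; it is a systems-level model,
  not a per-patient one (the dynamic states are per-patient but feed only
  the referral model).
- The null model conditions on the degree sequence and the forbidden-edge
  policy only; other structural constraints of a real ED (rosters, shift
  overlap) are not conditioned on, so "higher than chance" means higher
  than *this* chance model.
- Naive Bayes assumes feature independence given the class; correlated
  features (a node and its incident edges) share credit, which is one
  reason importance intervals are wide at this sample size.
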