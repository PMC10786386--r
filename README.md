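# carepath

Network modelling of clinical interactions along emergency-department (ED)
patient trajectories, aimed at health-services researchers studying how
clinical information flows around presentations with risk of suicide or
self-harm. Starting from a timestamped observational event log (who
interacted with whom, which information systems were accessed, and what
action resulted), the package builds network models of the care process and
asks three questions: which agents are structurally critical for information
flow, how fragile is the system to losing them, and which interactions
predict the handover from emergency medicine to emergency psychiatry.

## What it computes

**Event logs and trajectory statistics.** One row per observed interaction:
patient, care setting (ED or the adjacent Mental Health Observational Area,
MHOA), presentation mode, date/time, agents, information systems, resulting
action. Per-trajectory summaries (trajectory time, interaction counts,
distinct clinical staff types) use cohort medians with empirical 95%
intervals; MHOA-only patients are excluded from ED analyses.

**Clinical interaction network.** An undirected simple graph on agents and
information systems with an edge wherever a pair interacted at least once,
subject to a forbidden-edge policy (no system–system edges, systems connect
only to clinical staff, psychiatry-restricted systems connect only to
Emergency Psychiatry staff). On the adjacency matrix *A* with *n* nodes:

- degree centrality `k_i = Σ_j a_ij`
- closeness centrality `c_i = (n − 1) / Σ_j d_ij` (Wasserman–Faust scaled on
  disconnected graphs)
- betweenness centrality `b_i = Σ_{j<k} σ(j,k|i)/σ(j,k)` normalized by
  `(n − 1)(n − 2)/2`
- global efficiency `g = 1/(n(n−1)) Σ_{i≠j} 1/d_ij`
- greedy (agglomerative) modularity communities with a deterministic
  tie-break.

**Vulnerability analysis.** A degree-preserving null model by *constrained
connected double-edge swaps* (swaps that would disconnect the graph or
create a forbidden edge are rejected); percentile significance of a node's
betweenness against the shuffled ensemble; efficiency and closeness impact
of node removal; and greedy edge restoration — add candidate edges one at a
time to maximize the efficiency gain, enumerating all optimal orderings
when ties occur.

**Referral prediction.** Along each referred patient's trajectory a
cumulative network state `A_{p,t}` is vectorized as
`X_{p,t} = [v_1 … v_n | a_{ij} (i < j)]`; the state at the referral
interaction is labelled positive. A Bernoulli naive Bayes classifier with
Laplace smoothing is scored by balanced accuracy
`½(TP/(TP+FN) + TN/(TN+FP))` over patient-grouped 80:20 resampling splits
with minority oversampling, and permutation feature importance identifies
the nodes and edges that predict referral.

**Synthetic data.** Because observational event logs of this kind cannot be
shared, a generator produces logs with the structure the analyses measure:
two clinical teams, a hub liaison agent (the Psychiatric Liaison Nurse,
PLN) mediating cross-team information flow, and referral events triggered
by planted interaction signatures. `study_scale_fixture()` pins the
bookkeeping to the emulated study scale (43 trajectories, 272 interactions;
36/213 in the ED; 20 referrals among 87 pre-referral states).

## Worked example

```r
library(carepath)

fx  <- study_scale_fixture()          # deterministic synthetic study
ed  <- exclude_mhoa_only_patients(fx$log)
print(ed)
#> Clinical event log: 213 interactions, 36 patients
#>   settings: ED=213

trajectory_statistics(ed)
#> Trajectory summary for 36 patients
#>   trajectory time: median 1.51 h [0.08, 4.46]
#>   interactions:    median 5 [2, 12]
#>   staff types:     median 5 [2, 8]

net <- build_interaction_network(ed)
head(node_centrality(net)[order(-node_centrality(net)$betweenness), ], 2)
#>                         node degree closeness betweenness
#> 13 Psychiatric Liaison Nurse     13 0.8095238   0.2957840
#> 9                    Patient     12 0.7727273   0.1770467

ens <- shuffle_ensemble(net, n_shuffles = 100, attempts = 20000, seed = 1)
betweenness_percentile_test(net, "Psychiatric Liaison Nurse", ens)
#> Betweenness of Psychiatric Liaison Nurse: 0.2958 at percentile 99.0
#> of the null (flagged, > 95th)

node_removal_impact(net, "Psychiatric Liaison Nurse")
#> Removal of Psychiatric Liaison Nurse: global efficiency 0.6917 -> 0.5993 (-13.37%)

ds  <- build_dynamic_states(ed)
imp <- permutation_importance(ds, n_splits = 1000, seed = 1)
print(imp, n = 2)
#> Referral model over 1000 grouped splits: mean balanced accuracy 0.865
#> Top features by mean permutation importance:
#>                 feature mean_importance lower95 upper95
#>  Patient File|Registrar          0.1033  0.0000   0.317
#>      Consultant|Patient          0.0901  0.0000   0.295
```

Read: the liaison nurse is the top node on every centrality and the only
node whose betweenness exceeds the 95th percentile of the degree-preserving
null, removing it costs 13% of global efficiency, and the two planted
referral-trigger interactions (Registrar with the Patient File, Consultant
with the Patient) rank first for predicting the psychiatric referral —
exactly the structure the generator plants.

A thin command-line front end ships in `inst/cli/carepath.R`
(`stats`, `build-net`, `simulate`, `shuffle-test`).

## Methods

See the vignette source in `vignettes/` for the modelling assumptions,
parameter choices, numerical conventions and known limitations.
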