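---
title: "Inferring stromal-hematopoietic crosstalk from paired expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stromal-hematopoietic crosstalk from paired expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromatch)
```

## The model

`stromatch` treats cell–cell communication inference as a constrained join
between three objects:

1. a **pair database** of curated gene pairs $(a, b)$ with role annotations
   (receptor / ligand / adhesion / unknown), keyed on locus-link (Entrez)
   numeric identifiers with a case-folded-symbol fallback;
2. a **population profile**: per gene, linear-scale RMA-normalised replicate
   intensities, their mean, and a presence flag derived from Affymetrix-style
   P/M/A detection calls;
3. a **stromal profile** of the same form for the feeder/niche cell.

A candidate interaction is a database pair together with an assignment of its
partners to the two cells such that the population-side partner passed a
differential gate *and* is present in the population, while the stroma-side
partner is present in the stroma. Both assignments are always tested: the
screen is explicitly bidirectional, because progenitors signal to the stroma
as well as the reverse. No interaction score beyond the raw intensities is
computed — the method's output is an auditable table, not a ranking model.

The asymmetry between the two sides is deliberate and mirrors how such
screens are run: the scientific question ("which stromal factors could act
on this population, and vice versa?") gates the *population* gene list
against the stromal reference, on the presumption that crucial stroma-derived
growth factors are not expressed by the hematopoietic cells themselves. The
stroma's expression state is consumed as-is. Pairs matching in both
orientations (autocrine candidates) are emitted with an `autocrine` flag
rather than suppressed: encoding the presumption is the gate's job, and a
user replacing the gate should not silently lose those rows.

### The differential gate

`differential_genes()` tests each shared gene on $\log_2(x + 1)$ (intensities
are linear and can sit near zero; the pseudo-count keeps the transform
finite). The default is a Welch $t$ with a variance floor of $10^{-8}$ —
transparent and assumption-light. A `moderated_t` option shrinks the pooled
per-gene variances toward an empirical-Bayes prior estimated by moment
matching on the log sample variances (`squeeze_variances()`), the standard
small-$n$ stabilisation for microarrays; the unit tests verify it against the
reference implementation in `limma`. The gate threshold defaults to raw
$p < 0.01$ with **no multiple-testing correction**, which reproduces the
classical screen's behaviour; a Benjamini–Hochberg switch exists but is off
by default because the gate is a recall-oriented pre-filter whose false
positives are subsequently constrained by database membership and stromal
presence, not a hypothesis test whose rejections are reported as discoveries.

Profiles transcribed from printed mean intensities have one "replicate", so
no test statistic is defined; `fold_change_gate()` is the documented fallback
(linear ratio in either direction, intensities floored at 1.0, `p_value`
recorded as the marker value 1.0). The packaged fixture analyses bypass the
gate entirely (`gate = NULL`, presence-only), since the fixture profiles
already contain exactly the genes that passed the original gate.

### Presence calls

A gene is present when its representing probe set has a `P` call in at least
one replicate — the most permissive reading of "presence in at least one";
`present_rule = "all"` tightens it. Marginal `M` calls count as absent by
default (`marginal_as_present` flips this); the choice is conservative and
matters only for genes hovering at detection limits.

### Probe-set aggregation

Arrays carry multiple probe sets per gene; printed summary tables carry one
value. `aggregate_probesets()` defaults to `max_mean` (the probe set with the
largest mean represents the gene), common microarray practice that is exact
on one-probe-per-gene data; `mean_of_means` is the alternative. Ties break on
the probe set name so aggregation is invariant to input row order.

## Downstream analyses

**Stage dynamics.** `classify_pairs()` collapses matched rows to unordered,
direction-free pairs and records the set of populations (default series
LT-HSC, MPP, LMPP, CLP, GMP, proB, preB, matureB) where each occurs. The
only classification the data supports without an arbitrary cutoff is binary:
*ubiquitous* (all stages) versus *restricted* (anything less); no "restricted
to ≤ k stages" parameter is offered because any k would be invented. The
lineage is branched (GMP is myeloid); ubiquity is computed on the flat label
set, and `stage_transition_report()` is only meaningful along the linear
path the user declares.

**Supportive-stroma screen.** `nominate_candidates()` filters the stroma-side
genes of a matched table by supportive-stroma level ≥ `min_intensity` and
supportive/non-supportive fold ≥ `min_fold`, with the non-supportive
intensity floored at 1.0. Defaults are fold 5 and level 100: on the packaged
pro-B fixtures this admits the two order-of-magnitude contrasts (CXCL12,
531-fold; BMP4, 20-fold) while excluding shared cytokines near 2-fold
(IL-7, 189 vs 92) — deliberately, since the screen's purpose is to find
factors that *distinguish* the supportive stroma. A single fold threshold
covers both the "exclusively expressed" case (floored denominator) and the
"expressed to a higher level" case; no separate presence dichotomy is
needed.

**Co-culture response filter.** `response_genes()` keeps genes whose level
exceeds `min_level` (default 100) in *at least one* condition — applied to
the maximum so strongly induced genes that start near zero survive — whose
fold (floored denominators) reaches `min_fold` (default 5), and, when both
profiles have ≥ 2 replicates, whose two-sample $p$ is below `alpha`
(default 0.05). With single-replicate profiles the $p$ clause is skipped
with a notice rather than silently dropped.

**ΔΔCt.** `ddct_fold_change()` implements
$\Delta\Delta C_T = (C_{T,GOI(ctrl)} - C_{T,ref(ctrl)}) -
(C_{T,GOI(sample)} - C_{T,ref(sample)})$, fold $= 2^{\Delta\Delta C_T}$,
pairing each gene-of-interest cycle with the reference-gene (HPRT) cycle of
its *own* culture — the standard reading of a normalisation written without
sample subscripts. The identities the implementation guarantees exactly:
equal cycles give fold 1; swapping sample and control inverts the fold.

## The synthetic generator

`simulate_interaction_study()` exists so every pipeline stage can be tested
with exact ground truth and no external data. Genes draw a baseline
$\log_2$ level $\mathcal N(7, 1)$ (linear ≈ 128, comfortably above the
presence threshold of 50) shared between the two cells; replicates add
$\mathcal N(0, 0.5)$ log2 noise; three replicates per cell match common
array-study practice. For a *planted* pair the population partner gains
+5 log2 (32-fold) in the population only — making it differentially
expressed against the stromal reference — and the stroma partner gains the
same in the stroma. *Decoy* pairs have one randomly chosen partner forced
about 3 log2 below the presence threshold in both cells, so they fail the
matcher's presence conditions by construction and truth labels are exact
rather than statistical. Pairs are drawn on disjoint gene sets (hence
`2 * n_pairs <= n_genes`), which keeps the truth unambiguous at the cost of
not modelling promiscuous ligands.

What passing the recovery bound (mean recall ≥ 0.95, false-discovery
proportion ≤ 0.05 over 20 seeds of the 200-gene / 40-pair / 20-planted
default) shows: the gate, the presence logic, the index, the bidirectional
matching and the bookkeeping compose correctly, and the Welch gate at
$p < 0.01$ has the power the effect size implies. What it does **not**
show: performance on real arrays, where effects are smaller and correlated,
probe sets misbehave, presence calls err in structured ways
(`call_flip_rate` models only unstructured corruption), and the pair
database itself is incomplete or wrong. The generator makes no attempt to
emulate probe-level structure, batch effects or spatial artifacts.

All randomness derives from the config seed through R's default
Mersenne-Twister stream; identical seeds reproduce studies bit-for-bit
across platforms.

## Numerical and interface choices

* Canonical gene keys are identifier strings (numeric Entrez when present,
  case-folded symbol otherwise, with a logged downgrade); all joins happen
  on these keys, never on display names.
* Pairs are deduplicated on the **unordered** key pair at load time with a
  warning; direction is decided at match time from role annotations, because
  the same two partners legitimately appear in either orientation.
* Output rows are unique on (population gene, stroma gene, direction) and
  sorted case-insensitively in the C locale by stroma symbol, then
  population symbol, then direction, so outputs are diffable across
  machines. File writers emit `#` comment headers (version, parameters,
  input digests — no timestamp) and round-trip byte-identically through the
  matching readers.
* Degenerate inputs are defined, not accidental: header-only tables load as
  empty objects; an empty gate or database yields an empty (warned) table;
  a comparator lacking a gene records `NA` without changing the row set;
  zero within-group variance meets a `1e-8` floor; fold ratios meet a 1.0
  intensity floor.

## Problem sizes

The packaged validation runs at desk scale, chosen so the full suite stays
interactive: eight fixture tables of 8–22 rows against a 37-pair database,
matcher-versus-brute-force equivalence on 200 random instances of up to 50
genes and 25 pairs, and 20-seed recovery sweeps of the 200-gene default
simulation. The implementation is vectorised over database records and
gene vectors; nothing in it is specific to these sizes, and profiles of
array scale (tens of thousands of genes, hundreds of pairs) are handled by
the same code paths.

## Known limitations

* Expression is a proxy: matched transcripts do not demonstrate secretion,
  surface display, complex assembly or signalling competence. The output is
  a candidate list for functional follow-up, which is exactly how the
  in vitro screens that motivate the defaults use it.
* The screen inherits the pair database's scope and errors; it cannot find
  an interaction it was not given, and role annotations drive only the
  `direction` label, not admission.
* Single-replicate data cannot support the statistical gate; the fold gate
  is a transparent but weaker substitute.
* RMA normalisation and detection-call computation are consumed, not
  performed; profiles from different normalisation pipelines should not be
  mixed within one analysis.
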