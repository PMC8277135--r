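---
title: "Methods: causal maps, Bayesian networks, and mortality combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal maps, Bayesian networks, and mortality combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seabedrisk)
```

# The problem and the model

Environmental risk assessment of seabed mining must estimate the probability
of ecological harm for an activity with no observational record. The
workflow implemented here treats the assessment as two linked stages: a
qualitative *risk identification* stage in which each expert's causal map is
encoded, harmonized and merged into a combined causal network, and a
quantitative stage in which a subnetwork is expressed as a discrete Bayesian
network (BN) and queried under mining scenarios.

A BN factorizes the joint distribution over its variables by the chain rule:
every random variable carries a conditional probability table (CPT) given
its parents. Decision variables — mining intensity, depth of extracted
sediment, processing return technique — describe choices made by the
operator; they carry **no** prior. A query must fix them (a scenario) or
supply an explicit policy; the default policy used by the scenario engine is
uniform and is always logged, because averaging over an operator's choices
is a modelling statement, not an observation.

Inference is exact. `bn_posterior()` runs variable elimination on
data-frame factors with a greedy smallest-factor ordering; posteriors are
invariant to the ordering (property-tested) and equal full enumeration to
below 1e-9 on seeded random networks of up to 8 nodes (200 cases in the
acceptance suite). Evidence with zero marginal likelihood is an error, not a
silent NaN.

# Combining causal maps

Expert maps are directed edge lists with optional 1–3 strengths. Three
rules, each motivated by how elicited maps actually misalign:

* **Harmonization** maps raw labels ("worms", "polychaetes") onto canonical
  vocabulary ("mobile infauna"). The synonym table must be closed after one
  application, so harmonization is idempotent. Links made parallel by
  relabeling collapse to one link keeping the **maximum** strength — the
  elicitation gives no reconciliation rule, so we keep the most precautionary
  value while retaining every original strength in the per-expert provenance
  records, and the merge output flags the max rule. Links collapsed onto a
  self-loop are dropped and logged.
* **Missing strengths stay missing.** Not all strengths were elicited;
  imputing 1 would silently call every unrated link "weak".
* **Merging** is the non-redundant union of nodes and links. Support counts
  count contributing records; merge is order-independent. Cycles are allowed
  here — acyclicity is only a BN requirement.

# The 18-node quantitative model

The quantitative model describes acute (single time step, discrete mining
block, spatially homogeneous) impacts on three benthic functional groups.
Twelve named variables plus a three-node mortality decomposition per group
(direct, indirect, total) give 18 nodes. The full wiring of the original
fitted model is not published in printable form, so
`default_bn_structure()` is a documented reconstruction: intensity drives
volume of extraction and direct mortality; volume, sediment type, and
return technique drive suspended sediment and deposition; contaminants in
sediment plus suspended sediment drive contaminant release; the three
pressures drive each group's indirect mortality; direct and indirect drive
total. The model file is data — users can declare any other wiring,
including the published one imported via `read_cpt_table()`.

Two readings the state definitions force:

* Mining intensity is modelled with three states (50 / 75 / 100 % removed),
  since scenarios distinguish 50 % from 75 %.
* The "60–80 %" label that sometimes appears for the fourth mortality class
  is read as 61–80 %, so the five classes tile 0…100 without gaps.

# Mortality on the 1 % grid

Total mortality is `T = D + I(1 − D)`: the indirect pressure kills a
fraction of what direct extraction left. Numerically this is evaluated at
1 % accuracy. Choices a maintainer should know:

* **Within-class distribution is uniform** over the integer percents of the
  interval (class widths 11, 20, 30, 20, 20 grid points). The source is
  silent on this; uniform adds no information, and the expansion is
  swappable by supplying grid distributions directly.
* **Rounding is half-up** to the nearest integer percent, and classes bin by
  interval containment (80 → 61–80 %, 81 → 81–100 %).
* **Independence of D and I given their parents** is implicit in the product
  formula and is carried over.
* Direct mortality is a **point mass** at the intensity percent
  ("proportionate to the mined area"); an optional dispersion widens it over
  a symmetric truncated-normal window that shrinks near the grid boundary so
  the mean always equals the stated intensity.

The resulting 25-row total-mortality CPT is deterministic, mass-conserving
to 1e-9, and total stochastically dominates both parents on the grid —
all verified against an independent 101×101 double-loop enumeration.

# CPT initialization from ranked influences

The original tables were initialized with a graphical elicitation tool whose
scoring internals are not published. `initialize_cpt()` is therefore a
**documented stand-in**, not a reimplementation of that tool: each parent
contributes `weight × direction × rank01(state)` (nominal parents use
per-state offsets instead of a direction); the summed score is rescaled over
its attainable range to [0, 1] and becomes the centre of a truncated-normal
kernel over child state indices with standard deviation `spread`
(state-index units). The default `spread = 1.0` keeps a neutral score spread
over at least three of five states with mass ≥ 0.05, reflecting the low
certainty the elicitation reported — narrow defaults would manufacture
confidence. The baseline vector is used verbatim only when the ranking
carries no influence at all (zero score range); rows adjusted by an expert
(`adjust_cpt()`) always replace initialized rows verbatim and are audited.

`random_cpt()` draws rows from a symmetric Dirichlet; with
`monotone = TRUE` the CDF columns are sorted across score-ordered parent
combinations. Sorting each CDF column preserves row-wise monotonicity
(order statistics of pointwise-ordered sequences), so the sorted rows remain
valid distributions and form a full pairwise first-order
stochastic-dominance chain — a stronger guarantee than sorting by means,
which the property tests would reject.

# Scenarios and stressor ranking

A scenario assigns states to decision variables, optionally plus evidence on
random variables (scenario B adds `contaminant_release = significant` as
evidence, matching "with release of harmful substances"). Neither headline
scenario fixes the processing return technique; it is resolved by the logged
uniform policy, and users reproducing a published run should fix it
explicitly.

Stressor ranking needed an effect-size metric (none is named in the source):
we use the difference in class-midpoint expected mortality (midpoints 5,
20.5, 45.5, 70.5, 90.5) between the stressor's extreme states, computed as
max − min across the swept states so the effect is nonnegative even for
non-monotone responses, with the total-variation distance between the two
extreme posteriors reported alongside. Non-ancestors of the target get a
warning and effect 0.

# What the synthetic generator does and does not establish

The generator emulates the *statistical shape* of the elicited material: 11
experts, map sizes drawn from 8–24, links drawn from a hidden consensus
graph of 53 variables and 96 connections built deterministically from the
category structure (operational factors → pressures → biota, conditions
modulating both), strengths on 1–3 with ~35 % missing, raw-label synonyms at
rate 0.25, monotone pressure→mortality CPTs. With coverage enforcement the
union of the maps recovers the consensus exactly, giving the merge stage a
ground truth. Values not stated anywhere (noise rate 0, alias rate 0.25,
Dirichlet concentration 1) were fixed once at levels typical of such
elicitations and are documented in `synthetic_config()`.

What a green test therefore establishes: the pipeline's algebra (merge,
inference, grid combination) is correct, deterministic, and monotone where
the construction implies monotonicity. What it does **not** establish: any
empirical claim about Baltic benthos. The packaged fixtures are synthetic
stand-ins (filenames carry `_synthetic`); the published posterior
percentages can only be reproduced by importing the authors' fitted CPTs,
for which the delimited-CPT importer and the model-file format are provided.

# Numerical conventions and limitations

* Probability tolerance 1e-9 for all row sums and posteriors; CPT rows are
  never silently renormalized.
* Argmax ties break toward the earlier-ordered (lower-severity) state and
  are flagged.
* Model files store probabilities with 17 significant digits, so
  read → write → read is bit-identical.
* Scope excludes recovery, chronic and food-web effects, spatial plume
  structure, and sublethal endpoints: the model addresses acute mortality in
  one discrete block at one moment.
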