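---
title: "Ligand-centric target fishing: model, benchmark design, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-centric target fishing: model, benchmark design, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbench)
```

## The method and its assumptions

`tfbench` implements the simplest credible ligand-centric target-fishing
method, intended as a performance *floor* for more sophisticated approaches:

1. Encode every molecule as a 166-key structural fingerprint — a fixed
   dictionary of substructural features, each contributing one bit.
2. Score the query against every database molecule with the Dice
   coefficient, `2c/(a+b)`, where `a` and `b` are the two on-bit counts and
   `c` the shared on-bit count.
3. Take the top `k` database molecules and return the deduplicated union of
   their known targets as the predicted target set.

The method rests on the molecular similarity principle: structurally
similar molecules tend to share targets. Its two known failure modes are
inherited directly: *activity cliffs* (similar structures, divergent
activity) generate false positives, and incomplete testing of the neighbor
molecules generates false negatives. Neither is a bug of the implementation;
they are what the benchmark is designed to measure.

A *known target* is defined by the qualification filters in
`filter_criteria()`: a direct single-protein binding measurement
(EC50/Ki/Kd/IC50, exact `=` relation, nM units, binding assay type "B",
curator confidence 9) with potency at or below a threshold. The two
conventional thresholds are 1 uM and 10 uM. Values exactly equal to the
threshold qualify (the cutoff excludes activity *above* the threshold).
Replicate measurements for the same (molecule, target) pair are resolved
permissively: the pair qualifies if **any** single measurement qualifies.
This is a design choice — sources rarely state an aggregation rule — and it
is the reading most consistent with "hitting a target" being an existential
statement about potency.

## Evaluation model

Each query molecule defines one binary classification problem over the
**target universe**: all targets with at least `min_ligands` qualifying
ligands under the partition's criteria (`min_ligands = 1` for a
ligand-centric method, so the universe is every target in the map). The
query's known targets are the ground truth; every universe target falls in
exactly one confusion cell, so `TP+FP+FN+TN` equals the universe size,
`TP+FP = NPT`, and `TP+FN = NKT`. From the cells we report accuracy,
precision, recall and MCC per query, and arithmetic means over evaluable
queries as the aggregate. Unevaluable queries (no fingerprint) are listed
with reasons and never imputed.

This per-query formulation is deliberately *not* a ROC/AUC evaluation: the
quantities practitioners act on are "how many predictions must I test to
find a true target" (precision) and "how many known targets does the method
miss" (recall), both per query molecule.

Ground truth is itself an undercount: a query has typically been tested
against a tiny fraction of the universe, so unconfirmed predictions are
scored as false positives even though some would validate if tested.
Measured performance is therefore a lower bound, and the benchmark makes
the mechanism visible (see the observation-bias section below).

Benchmark partitions keep query and database sets disjoint, and
`make_partitions()` pairs every designated query set with a same-size
random control drawn uniformly (without replacement) from the remaining map
molecules; the database — identical for both partitions — is everything
else. The sampling pool excludes the designated queries. Whether a real
curation would also exclude them from the *control* draw is ambiguous;
excluding them is recorded in the partition object via its seed and the
criteria provenance.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `threshold_nM` | 10000 | the looser of the two conventional potency cutoffs; 1000 for the strict variant |
| `allowed_activity_types` | EC50, Ki, Kd, IC50 | dose-response endpoints; percent-inhibition style readouts are not comparable |
| `min_ligands` | 1 | ligand-centric floor; raise to emulate model-based method classes (5–40) |
| `k` | 1, 5, 10, 15 | the method's only control parameter; precision falls and recall rises with k |
| Dice tie-break | ascending molecule id | determinism; similarity scores tie often on 166 bits |

## Numerical and edge-case conventions

* **Dice of two empty fingerprints is 0**, not 1: a molecule with no
  detected features should not match everything.
* **Rankings** sort by descending score with ties broken by ascending
  molecule id; `top_k` counts molecules, never targets, and tied molecules
  at the k-th boundary are resolved by the same rule.
* **Degenerate metrics** are flagged zeros rather than NaN: precision when
  nothing was predicted (`precision_undefined`), recall when the query has
  no known targets (`recall_undefined`), MCC when any factor of the
  denominator is zero (`mcc_degenerate`). Flags travel with the per-query
  table so averages cannot be silently poisoned.
* **Quartiles** use the linear-interpolation convention (R type 7);
  boxplot outliers use 1.5 x IQR Tukey fences.
* **Fingerprint cache** stores each molecule as 42 hexadecimal characters
  (166 bits + 2 zero padding bits, MSB-first nibbles); unavailable
  molecules are cached with their reason so reruns skip re-parsing.
* **Unparseable and multi-component (dot-disconnected) SMILES** yield an
  unavailability marker, never an exception: mixtures have no single
  fingerprint, mirroring the exclusion of multi-compound preparations from
  similarity search.

## What the synthetic generator emulates — and what it does not

`generate_database()` builds a world with known ground truth:

* **Chemical series**: each series has a prototype fingerprint
  (Bernoulli(0.25) bits — roughly the key density of drug-like molecules);
  members flip each bit with probability `bitflip_noise` (default 0.02,
  small within-series structural variation). Series share a target set.
* **Heavy-tailed polypharmacology**: with probability 0.05 a molecule is
  promiscuous and gains `NegBinom(size = 0.3, mu = 20)` extra cross-series
  targets. The small `size` yields the multi-hundred-target outliers real
  curations contain, while typical molecules keep a handful of targets
  (series sets of `1 + Poisson(2)`).
* **Potencies**: log-uniform on 1 nM – 100 uM, so a 10 uM threshold
  filters a realistic fraction of measured pairs.
* **Observation bias**: `bias_mask()` retains each true pair independently
  with a role-dependent rate (`observation_rate_query` vs
  `observation_rate_db`), modelling the deeper target panels that drug-like
  molecules are tested against. Draws are keyed per pair, so masks nest
  across rates under one seed.
* **Filter exercise**: a configurable fraction of *extra* deliberately
  disqualified rows (censored relation, wrong units, low confidence, ...)
  duplicates existing pairs, so qualification filters are exercised without
  corrupting ground truth.

One master seed feeds independent per-stage substreams (series sizes,
fingerprints, promiscuity, potencies, mask), so changing one stage's draw
count does not perturb the others.

What it does **not** emulate: real medicinal chemistry (scaffolds,
physicochemical property distributions), activity cliffs beyond plain bit
noise, correlated target panels, or assay-level noise. A green end-to-end
test therefore establishes that the pipeline is *correct* — filters,
similarity, transfer and scoring compose as specified — not that the
method performs at any particular level on real curated data.

### The exact-transfer regime

The end-to-end smoke oracle uses a world where annotation transfer is
provably exact: `bitflip_noise = 0`, both observation rates 1, promiscuity
off, **and potencies bounded by the threshold** (`activity_range =
c(1, 1e4)` against a 10 uM cutoff). The last condition matters: with
potencies spanning beyond the threshold, each pair survives qualification
independently, so series mates no longer carry identical qualifying sets
and exactness fails for reasons unrelated to the method. In that regime,
provided every query keeps at least `k` series mates in the database, all
per-query metrics equal 1.

### Direction of the observation-bias effect

Hiding annotations on the **query side** (lower `observation_rate_query`)
removes entries from the ground truth while the neighbors still vouch for
them, so correct predictions are scored as false positives: measured
precision falls. This is the mechanism by which heavily-tested molecules
(approved drugs) score *worse* than randomly chosen molecules of equal
intrinsic promiscuity. Hiding annotations on the **database side** thins
what the hits can transfer: predictions shrink, recall falls, and — with
fully observed queries — precision is not pushed down, because the
surviving transferred targets remain subsets of the truth. The paired
directional test in the acceptance suite accordingly masks the query side
and asserts a strict precision drop over 200 queries.

## Known limitations

* Fingerprint generation requires a Python/RDKit toolchain on `PATH`; the
  rest of the package (including the full synthetic benchmark) is pure R.
* Bit-level fingerprints depend on the key-dictionary release of the
  toolkit; rankings are reproducible within an environment, not guaranteed
  across toolkit versions.
* The baseline carries no per-target score or cutoff; weighted transfer
  and per-target calibrated methods are out of scope by design — this is
  the floor they should beat.
* Aggregates are plain means over evaluable queries; no significance
  testing between partitions is provided.
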