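# tfbench

Ligand-centric target fishing with a per-query-molecule benchmark.

## The problem

Target fishing (TF) — also called target prediction or polypharmacology
prediction — asks the reverse question of virtual screening: given a small
molecule, which macromolecular targets does it hit? A *ligand-centric*
answer needs no model per target: rank a large database of target-annotated
molecules by chemical similarity to the query and transfer the annotations
of the nearest neighbors. Because it can interrogate any target with at
least one known ligand, a ligand-centric search covers thousands of targets
that model-based (target-centric) methods are structurally blind to.

`tfbench` implements that baseline and, more importantly, the evaluation
framework around it:

* **Curation** — explicit qualification filters on a bioactivity table: a
  (molecule, target) pair counts as a *known target* only through a direct
  single-protein binding measurement (EC50/Ki/Kd/IC50, `=` relation, nM
  units, assay type B, top curator confidence) with potency at or below a
  threshold (1 uM or 10 uM), and only targets with at least *n* qualifying
  ligands enter the target universe.
* **Prediction** — 166-key structural fingerprints (MACCS dictionary, via
  RDKit), Dice similarity `2c/(a+b)`, and the deduplicated union of the
  known targets of the top-*k* hits as the predicted set
  (*k* = 1, 5, 10, 15).
* **Evaluation** — each query is a binary classification over the target
  universe: TP/FP/FN/TN with `TP+FP = NPT` (number of predicted targets)
  and `TP+FN = NKT` (number of known targets), scored by accuracy,
  precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and the Matthews correlation
  coefficient; benchmark partitions keep query and database molecules
  disjoint and pair every designated query set with a same-size random
  control.
* **Coverage** — how many targets a method class restricted to
  `min_ligands` = 5…40 neglects relative to the ligand-centric floor of 1.
* **Simulation** — a synthetic chemogenomics generator (chemical series,
  heavy-tailed polypharmacology, log-uniform potencies, observation-bias
  masks) with full ground truth, so the entire pipeline is testable with no
  external database.

It is aimed at method developers who want to compare a TF method against an
honest, reproducible baseline, and at anyone studying how *observed
polypharmacology* — intrinsic promiscuity confounded with testing depth —
shapes measured performance.

## Worked example

A fully synthetic world: 40 chemical series of 6 molecules, 2% fingerprint
bit noise, potencies log-uniform on 1–10,000 nM. One molecule per series is
a designated query; the benchmark draws a same-size random control.

```r
library(tfbench)

cfg <- synthetic_config(n_series = 40, molecules_per_series = 6,
                        bitflip_noise = 0.02, activity_range = c(1, 1e4), seed = 7)
db  <- generate_database(cfg)

f <- tempfile(fileext = ".csv"); write_synthetic_activity(db, f)
map <- apply_selection_filters(load_activity_table(f),
                               filter_criteria(threshold_nM = 10000))
map
#> <known-target map: 240 molecules, 132 targets, 994 pairs>

parts <- make_partitions(map, db$queries, seed = 7)
res   <- run_benchmark(parts$designated, db$fingerprints, map, k = 5)
res
#> <benchmark 'designated' k=5: 40 queries (0 unevaluable), universe 132>
#>   avNPT=8.78 avAccuracy=0.938 avPrecision=0.537 avRecall=0.953 avMCC=0.657

head(res$per_query[, c("query_id","NKT","NPT","TP","FP","FN","precision","recall","mcc")], 3)
#>    query_id NKT NPT TP FP FN precision recall       mcc
#> 1 MOL000001   2   3  2  1  0 0.6666667      1 0.8133501
#> 2 MOL000007   5   7  5  2  0 0.7142857      1 0.8384731
#> 3 MOL000013   3  11  3  8  0 0.2727273      1 0.5057805
```

Reading the aggregate row: on average a query's top-5 hits propose 8.8
targets (avNPT), about half of which are confirmed (avPrecision 0.54),
while 95% of its known targets are recovered (avRecall). Accuracy is
high mostly because the classification is extremely unbalanced — nearly
every universe target is a correctly rejected non-target.

Polypharmacology and case-study reporting:

```r
summarize_stats(res$per_query$NKT, res$per_query$query_id)
#> <n=40 mean=6.08 median=3 [q1=2 q3=4.25] range=[1, 81], 3 outlier(s)>

p <- res$predictions[["MOL000001"]]
overlap_report(p, known_targets(map, "MOL000001"))
#> <overlap for MOL000001 (k=5): NKT=2 NPT=3 | TP=2 FP=1 FN=0>
```

The NKT summary shows the heavy tail the generator builds in: median 3
known targets but a 81-target promiscuous outlier. The overlap report names
the targets behind each confusion cell (here: both known targets recovered,
one unconfirmed prediction).

## Command line

The same workflow as subcommands (`exec/tfbench`, or `Rscript -e
'tfbench::tf_cli()' --`):

```sh
tfbench simulate  --seed 7 --n-series 40 --out-dir sim/
tfbench build-db  --activity sim/activity.csv --cache sim/fp_cache.tsv \
                  --threshold 10000 --out-dir db/
tfbench fish      --db-dir db/ --query-smiles 'CC(=O)Oc1ccccc1C(=O)O' --k 5
tfbench benchmark --db-dir db/ --queries sim/queries.txt --k 1,5,10,15 \
                  --seed 7 --out-dir bench/
tfbench coverage  --activity sim/activity.csv --methods methods.csv --out cov.csv
```

Every run writes a `provenance.json` (criteria, k, seed, input digests).
Exit codes: 0 ok, 1 configuration error, 2 I/O error, 3 query fingerprint
unavailable.

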