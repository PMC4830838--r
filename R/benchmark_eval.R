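#' Construct a benchmark partition explicitly
#'
#' Query and database molecule sets must be disjoint and known to the map.
#' [make_partitions()] builds the designated/random-control pair used in a
#' full benchmark; this constructor is for bespoke partitions (e.g. using
#' every non-query molecule as the database).
#'
#' @param known_map a `known_target_map`.
#' @param query_ids,database_ids disjoint character vectors of molecule ids
#'   present in the map; `database_ids` defaults to all other map molecules.
#' @param label partition label.
#' @param seed integer recorded for provenance (no randomness is drawn here).
#' @return a `benchmark_partition`.
#' @export
benchmark_partition <- function(known_map, query_ids,
                                database_ids = setdiff(names(known_map$forward), query_ids),
                                label = "custom", seed = 0L) {
  stopifnot(inherits(known_map, "known_target_map"))
  query_ids <- unique(as.character(query_ids))
  database_ids <- unique(as.character(database_ids))
  if (length(intersect(query_ids, database_ids))) {
    stopf("query and database molecule sets must be disjoint")
  }
  absent <- setdiff(c(query_ids, database_ids), names(known_map$forward))
  if (length(absent)) {
    stopf("molecule(s) not in the map: %s", paste(head(absent, 5), collapse = ", "))
  }
  structure(list(label = label, criteria = known_map$criteria,
                 query_ids = sort(query_ids), database_ids = sort(database_ids),
                 seed = as.integer(seed)),
            class = "benchmark_partition")
}

#' Build benchmark partitions with a random control group
#'
#' Given a designated query set (e.g. approved drugs), draws a same-size
#' random control uniformly without replacement from the remaining map
#' molecules, and assigns everything else to the searchable database —
#' identical for both partitions. No query molecule is ever a database
#' molecule.
#'
#' @param known_map a `known_target_map`.
#' @param designated_queries character vector of molecule ids present in the
#'   map.
#' @param seed integer; the control draw is fully reproducible from it.
#' @param labels length-2 labels for the designated and control partitions.
#' @return list of two `benchmark_partition` objects (`designated`,
#'   `control`), each with `label`, `criteria`, `query_ids`, `database_ids`,
#'   `seed`.
#' @export
make_partitions <- function(known_map, designated_queries, seed,
                            labels = c("designated", "random-control")) {
  stopifnot(inherits(known_map, "known_target_map"))
  designated_queries <- unique(as.character(designated_queries))
  molecules <- sort(names(known_map$forward))
  absent <- setdiff(designated_queries, molecules)
  if (length(absent)) {
    stopf("designated query molecule(s) not in the map: %s",
          paste(head(absent, 5), collapse = ", "))
  }
  pool <- setdiff(molecules, designated_queries)
  if (length(pool) < length(designated_queries)) {
    stopf("map too small: %d molecules cannot hold 2 x %d query sets",
          length(molecules), length(designated_queries))
  }
  control <- with_seed(seed, sample(pool, length(designated_queries)))
  database <- setdiff(pool, control)
  part <- function(label, queries) {
    structure(list(label = label, criteria = known_map$criteria,
                   query_ids = sort(queries), database_ids = database,
                   seed = as.integer(seed)),
              class = "benchmark_partition")
  }
  list(designated = part(labels[1], designated_queries),
       control = part(labels[2], control))
}

#' @export
print.benchmark_partition <- function(x, ...) {
  cat(sprintf("<partition '%s': %d queries, %d database molecules, seed %d>\n",
              x$label, length(x$query_ids), length(x$database_ids), x$seed))
  invisible(x)
}

#' Confusion counts of one query's prediction over the target universe
#'
#' Each target in the universe falls in exactly one cell: TP (predicted and
#' known), FP (predicted, not known), FN (known, not predicted), TN
#' (neither). Hence TP+FP = NPT, TP+FN = NKT and the four cells always sum
#' to the universe size.
#'
#' @param predicted,known character vectors of target ids, both subsets of
#'   `universe`.
#' @param universe character vector: all qualifying targets under the
#'   partition's criteria.
#' @return a `confusion_counts` list: `TP`, `FP`, `FN`, `TN`,
#'   `universe_size`.
#' @export
confusion_matrix <- function(predicted, known, universe) {
  predicted <- unique(as.character(predicted))
  known <- unique(as.character(known))
  universe <- unique(as.character(universe))
  if (length(setdiff(known, universe))) {
    stopf("known targets outside the universe: inconsistent criteria")
  }
  if (length(setdiff(predicted, universe))) {
    stopf("predicted targets outside the universe: inconsistent criteria")
  }
  tp <- length(intersect(predicted, known))
  fp <- length(predicted) - tp
  fn <- length(known) - tp
  tn <- length(universe) - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 universe_size = length(universe)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FP=%d FN=%d TN=%d (universe %d)>\n",
              x$TP, x$FP, x$FN, x$TN, x$universe_size))
  invisible(x)
}

#' Per-query classification metrics
#'
#' Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate denominators do not poison averages silently: precision is 0
#' with a `precision_undefined` flag when nothing was predicted, recall 0
#' with `recall_undefined` when the query has no known targets, and MCC 0
#' with `mcc_degenerate` when any factor under the root is 0.
#'
#' @param cc a [confusion_matrix()] result.
#' @return a `query_metrics` list: `accuracy`, `precision`, `recall`, `mcc`,
#'   `flags` (character vector, possibly empty).
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc$TP; fp <- cc$FP; fn <- cc$FN; tn <- cc$TN
  n <- cc$universe_size
  if (n < 1) stopf("empty target universe")
  flags <- character()
  accuracy <- (tp + tn) / n
  if (tp + fp == 0) {
    precision <- 0; flags <- c(flags, "precision_undefined")
  } else precision <- tp / (tp + fp)
  if (tp + fn == 0) {
    recall <- 0; flags <- c(flags, "recall_undefined")
  } else recall <- tp / (tp + fn)
  denom <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    mcc <- 0; flags <- c(flags, "mcc_degenerate")
  } else {
    mcc <- (as.double(tp) * tn - as.double(fp) * fn) / sqrt(denom)
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 mcc = mcc, flags = flags),
            class = "query_metrics")
}

#' Five-number summary with Tukey outliers
#'
#' Boxplot-style summary of a per-query statistic: mean, median, quartiles
#' (linear-interpolation convention, R type 7), extremes, and the ids of
#' values beyond the 1.5 x IQR Tukey fences.
#'
#' @param values non-empty numeric vector.
#' @param ids optional parallel id vector for outlier reporting.
#' @return a `summary_stats` list: `n`, `mean`, `median`, `q1`, `q3`, `min`,
#'   `max`, `outlier_ids`.
#' @export
summarize_stats <- function(values, ids = NULL) {
  if (!length(values)) stopf("cannot summarize an empty vector")
  if (is.null(ids)) ids <- as.character(seq_along(values))
  stopifnot(length(ids) == length(values))
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  out <- values < q[1] - 1.5 * iqr | values > q[3] + 1.5 * iqr
  structure(list(n = length(values), mean = mean(values), median = q[2],
                 q1 = q[1], q3 = q[3], min = min(values), max = max(values),
                 outlier_ids = as.character(ids[out])),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<n=%d mean=%.3g median=%.3g [q1=%.3g q3=%.3g] range=[%.3g, %.3g], %d outlier(s)>\n",
              x$n, x$mean, x$median, x$q1, x$q3, x$min, x$max,
              length(x$outlier_ids)))
  invisible(x)
}

#' Run the per-query benchmark on one partition
#'
#' For every evaluable query: predict targets at `k` from the partition's
#' database, score the prediction as a binary classification over the
#' qualifying target universe, and compute the four metrics. The aggregate
#' row is the arithmetic mean over evaluable queries only; queries without a
#' fingerprint are listed with reasons, never imputed.
#'
#' @param partition a [make_partitions()] partition.
#' @param fingerprints an [fp_db()] covering (at least) the partition's
#'   molecules; database molecules without a fingerprint simply cannot be
#'   retrieved as hits.
#' @param known_map the `known_target_map` the partition was built from.
#' @param k positive integer.
#' @return a `benchmark_result`: `per_query` (data.frame: query_id, k, NKT,
#'   NPT, TP, FP, FN, TN, accuracy, precision, recall, mcc, flags),
#'   `aggregate` (list: k, n_queries, avNPT, avAccuracy, avPrecision,
#'   avRecall, avMCC), `unevaluable` (data.frame), `universe_size`,
#'   `predictions` (named list, for case-study reporting).
#' @export
run_benchmark <- function(partition, fingerprints, known_map, k) {
  stopifnot(inherits(partition, "benchmark_partition"),
            inherits(fingerprints, "fp_db"),
            inherits(known_map, "known_target_map"))
  universe <- target_universe(known_map, known_map$criteria$min_ligands)
  db <- fp_db_subset(fingerprints, partition$database_ids)
  queries <- lapply(stats::setNames(partition$query_ids, partition$query_ids),
                    fp_db_get, db = fingerprints)
  batch <- batch_predict(queries, db, known_map, k)
  rows <- lapply(batch$predictions, function(p) {
    known <- known_targets(known_map, p$query_id)
    cc <- confusion_matrix(p$predicted_targets, known, universe)
    m <- compute_metrics(cc)
    data.frame(query_id = p$query_id, k = p$k,
               NKT = length(known), NPT = length(p$predicted_targets),
               TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, mcc = m$mcc,
               flags = paste(m$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  per_query <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(query_id = character(), k = integer(), NKT = integer(),
               NPT = integer(), TP = integer(), FP = integer(), FN = integer(),
               TN = integer(), accuracy = numeric(), precision = numeric(),
               recall = numeric(), mcc = numeric(), flags = character(),
               stringsAsFactors = FALSE)
  aggregate <- list(
    label = partition$label, k = as.integer(k), n_queries = nrow(per_query),
    avNPT = mean(per_query$NPT), avAccuracy = mean(per_query$accuracy),
    avPrecision = mean(per_query$precision), avRecall = mean(per_query$recall),
    avMCC = mean(per_query$mcc)
  )
  structure(list(per_query = per_query, aggregate = aggregate,
                 unevaluable = batch$excluded,
                 universe_size = length(universe),
                 predictions = batch$predictions),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<benchmark '%s' k=%d: %d queries (%d unevaluable), universe %d>\n",
              a$label, a$k, a$n_queries, nrow(x$unevaluable), x$universe_size))
  cat(sprintf("  avNPT=%.2f avAccuracy=%.3f avPrecision=%.3f avRecall=%.3f avMCC=%.3f\n",
              a$avNPT, a$avAccuracy, a$avPrecision, a$avRecall, a$avMCC))
  invisible(x)
}

#' Targets neglected by a restricted method class
#'
#' A method class that needs `n_method`-sized training sets can only
#' interrogate its qualifying targets; a ligand-centric search at the same
#' activity threshold covers `n_ligand_centric`. The difference is the
#' number of targets the restricted class is blind to by construction.
#'
#' @param n_ligand_centric,n_method non-negative target counts, with
#'   `n_ligand_centric >= n_method`.
#' @return integer difference.
#' @examples
#' neglected_targets(3035, 917)  # 2118
#' @export
neglected_targets <- function(n_ligand_centric, n_method) {
  assert_scalar_number(n_ligand_centric, "n_ligand_centric")
  assert_scalar_number(n_method, "n_method")
  if (n_method < 0 || n_ligand_centric < n_method) {
    stopf("need n_ligand_centric >= n_method >= 0")
  }
  as.integer(n_ligand_centric - n_method)
}

#' Target-coverage table across method classes
#'
#' For each (min_ligands, threshold) method class, counts the qualifying
#' targets in the supplied records and the targets a ligand-centric search
#' (floor `ligand_centric_min`) covers at the same threshold; the neglect
#' column is their difference.
#'
#' @param records canonical record table ([load_activity_table()]).
#' @param methods data.frame with columns `min_ligands` and `threshold_nM`
#'   (one row per method class), optionally `label`.
#' @param criteria base [filter_criteria()]; threshold and floor are
#'   overridden per row.
#' @param ligand_centric_min ligand floor of the reference ligand-centric
#'   method (1).
#' @return data.frame with columns `label`, `min_ligands`, `threshold_nM`,
#'   `n_targets_method`, `n_targets_ligand_centric`, `n_neglected`.
#' @export
coverage_table <- function(records, methods, criteria = filter_criteria(),
                           ligand_centric_min = 1L) {
  stopifnot(is.data.frame(methods),
            all(c("min_ligands", "threshold_nM") %in% names(methods)))
  rows <- lapply(seq_len(nrow(methods)), function(i) {
    th <- methods$threshold_nM[i]
    crit_m <- filter_criteria(threshold_nM = th,
                              allowed_activity_types = criteria$allowed_activity_types,
                              required_relation = criteria$required_relation,
                              required_units = criteria$required_units,
                              required_assay_type = criteria$required_assay_type,
                              required_confidence = criteria$required_confidence,
                              required_target_type = criteria$required_target_type,
                              min_ligands = methods$min_ligands[i])
    map <- apply_selection_filters(records, crit_m)
    n_method <- length(target_universe(map, methods$min_ligands[i]))
    crit_lc <- crit_m; crit_lc$min_ligands <- as.integer(ligand_centric_min)
    map_lc <- apply_selection_filters(records, crit_lc)
    n_lc <- length(target_universe(map_lc, ligand_centric_min))
    data.frame(label = if ("label" %in% names(methods)) methods$label[i] else
                 sprintf("min%d_thr%g", methods$min_ligands[i], th),
               min_ligands = methods$min_ligands[i], threshold_nM = th,
               n_targets_method = n_method, n_targets_ligand_centric = n_lc,
               n_neglected = neglected_targets(n_lc, n_method),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Case-study overlap report
#'
#' Names the targets in each confusion cell for one query — the material of
#' a Venn-style overlap figure: which known targets were recovered (TP),
#' which predictions are unconfirmed (FP, with their supporting hits), and
#' which known targets the method missed (FN).
#'
#' @param prediction a `query_prediction`.
#' @param known character vector: the query's known targets.
#' @return an `overlap_report` list: `query_id`, `k`, `NKT`, `NPT`, `tp`,
#'   `fp`, `fn` (sorted character vectors), `support` (for predicted
#'   targets).
#' @export
overlap_report <- function(prediction, known) {
  stopifnot(inherits(prediction, "query_prediction"))
  known <- unique(as.character(known))
  predicted <- prediction$predicted_targets
  structure(list(query_id = prediction$query_id, k = prediction$k,
                 NKT = length(known), NPT = length(predicted),
                 tp = sort(intersect(predicted, known)),
                 fp = sort(setdiff(predicted, known)),
                 fn = sort(setdiff(known, predicted)),
                 support = prediction$support),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap for %s (k=%d): NKT=%d NPT=%d | TP=%d FP=%d FN=%d>\n",
              x$query_id, x$k, x$NKT, x$NPT,
              length(x$tp), length(x$fp), length(x$fn)))
  invisible(x)
}
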