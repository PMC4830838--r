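ten_mol_map <- function() {
  map_from_pairs(data.frame(molecule_id = sprintf("M%02d", 1:10),
                            target_id = rep(sprintf("T%d", 1:2), 5),
                            stringsAsFactors = FALSE))
}

test_that("make_partitions draws a disjoint same-size control, reproducibly", {
  map <- ten_mol_map()
  designated <- c("M01", "M04", "M07")
  parts <- make_partitions(map, designated, seed = 42)
  expect_equal(parts$designated$query_ids, designated)
  expect_equal(length(parts$control$query_ids), 3)
  expect_equal(length(parts$designated$database_ids), 4)
  expect_equal(parts$designated$database_ids, parts$control$database_ids)
  sets <- list(parts$designated$query_ids, parts$control$query_ids,
               parts$designated$database_ids)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(intersect(sets[[i]], sets[[j]]), character())
  }
  # determinism in the seed
  again <- make_partitions(map, designated, seed = 42)
  expect_identical(again$control$query_ids, parts$control$query_ids)
  different <- make_partitions(map, designated, seed = 43)
  expect_false(identical(different$control$query_ids, parts$control$query_ids))
})

test_that("make_partitions rejects maps too small to hold both query sets", {
  map <- ten_mol_map()
  expect_error(make_partitions(map, sprintf("M%02d", 1:6), seed = 1), "too small")
  expect_error(make_partitions(map, "NOT_THERE", seed = 1), "not in the map")
})

test_that("confusion_matrix partitions the universe into the four cells", {
  # promiscuous-drug worked example: 67 known, 9 predicted, 8 shared, 3035 universe
  universe <- sprintf("U%04d", 1:3035)
  known <- universe[1:67]
  predicted <- c(universe[1:8], universe[100])
  cc <- confusion_matrix(predicted, known, universe)
  expect_equal(cc$TP, 8)
  expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 59)
  expect_equal(cc$TN, 2967)

  # perfect prediction
  cc <- confusion_matrix(known, known, universe)
  expect_equal(cc$FP, 0)
  expect_equal(cc$FN, 0)

  # exhaustive small case
  cc <- confusion_matrix(c("T2", "T3"), c("T1", "T2"), sprintf("T%d", 1:5))
  expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]),
               c(TP = 1L, FP = 1L, FN = 1L, TN = 2L))

  expect_error(confusion_matrix("X", "T1", sprintf("T%d", 1:5)), "universe")
  expect_error(confusion_matrix("T1", "X", sprintf("T%d", 1:5)), "universe")
})

test_that("conservation TP+FP+FN+TN = universe holds on random fixtures", {
  withr::with_seed(600, {
    for (i in 1:25) {
      n <- sample(5:40, 1)
      universe <- sprintf("T%02d", seq_len(n))
      known <- sample(universe, sample(0:n, 1))
      predicted <- sample(universe, sample(0:n, 1))
      cc <- confusion_matrix(predicted, known, universe)
      expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, n)
      expect_equal(cc$TP + cc$FN, length(known))      # NKT
      expect_equal(cc$TP + cc$FP, length(predicted))  # NPT
    }
  })
})

test_that("compute_metrics reproduces the worked-example and closed forms", {
  universe <- sprintf("U%04d", 1:3035)
  cc <- confusion_matrix(c(universe[1:8], universe[100]), universe[1:67], universe)
  m <- compute_metrics(cc)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 8 / 67)
  expect_equal(m$flags, character())

  # perfect prediction on a non-trivial universe
  cc <- confusion_matrix("T1", "T1", c("T1", "T2"))
  m <- compute_metrics(cc)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "mcc")]),
               c(accuracy = 1, precision = 1, recall = 1, mcc = 1))

  # direct MCC evaluation: TP=1 FP=1 FN=1 TN=2 -> 1/6
  cc <- confusion_matrix(c("T2", "T3"), c("T1", "T2"), sprintf("T%d", 1:5))
  expect_equal(compute_metrics(cc)$mcc, 1 / 6)
})

test_that("degenerate denominators give flagged zeros, not NaN", {
  universe <- sprintf("T%d", 1:4)
  m <- compute_metrics(confusion_matrix(character(), "T1", universe))
  expect_equal(m$precision, 0)
  expect_equal(m$mcc, 0)
  expect_true("precision_undefined" %in% m$flags)
  expect_true("mcc_degenerate" %in% m$flags)

  m <- compute_metrics(confusion_matrix("T1", character(), universe))
  expect_equal(m$recall, 0)
  expect_true("recall_undefined" %in% m$flags)
  expect_false(any(is.nan(unlist(m[1:4]))))
})

test_that("metrics match exhaustive enumeration on small universes", {
  universe <- sprintf("T%d", 1:5)
  subsets <- lapply(0:31, function(m) universe[bitwAnd(m, 2^(0:4)) > 0])
  for (known in subsets) for (predicted in subsets) {
    cc <- confusion_matrix(predicted, known, universe)
    # independent oracle: classify each target by direct membership tests
    cells <- table(factor(paste0(
      ifelse(universe %in% predicted, "P", "n"),
      ifelse(universe %in% known, "K", "u")
    ), levels = c("PK", "Pu", "nK", "nu")))
    expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), unname(as.vector(cells)))
    m <- compute_metrics(cc)
    tp <- cells[["PK"]]; fp <- cells[["Pu"]]; fn <- cells[["nK"]]; tn <- cells[["nu"]]
    expect_equal(m$accuracy, (tp + tn) / 5)
    expect_equal(m$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(m$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
    d <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    expect_equal(m$mcc, if (d > 0) (tp * tn - fp * fn) / sqrt(d) else 0)
  }
})

test_that("summarize_stats uses linear quartiles and Tukey fences", {
  s <- summarize_stats(7, ids = "only")
  expect_equal(unlist(s[c("mean", "median", "q1", "q3", "min", "max")]),
               c(mean = 7, median = 7, q1 = 7, q3 = 7, min = 7, max = 7))
  expect_equal(s$outlier_ids, character())

  s <- summarize_stats(c(1, 2, 3, 4, 100), ids = c("a", "b", "c", "d", "e"))
  expect_equal(s$median, 3)
  expect_equal(s$mean, 22)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$outlier_ids, "e")

  # appending a value equal to the median leaves the median unchanged
  expect_equal(summarize_stats(c(1, 2, 3, 4, 100, 3))$median, 3)
  expect_error(summarize_stats(numeric()), "empty")
})

test_that("run_benchmark matches a full manual trace on a handcrafted fixture", {
  map <- map_from_pairs(data.frame(
    molecule_id = c("Q1", "Q1", "D1", "D2", "D2", "D3"),
    target_id = c("T1", "T2", "T1", "T2", "T3", "T4"),
    stringsAsFactors = FALSE
  ))
  fps <- fp_db(list(Q1 = make_fp(1:10), D1 = make_fp(1:10),
                    D2 = make_fp(1:8), D3 = make_fp(100:120)))
  part <- benchmark_partition(map, "Q1", c("D1", "D2", "D3"), label = "trace")
  res <- run_benchmark(part, fps, map, k = 2)
  row <- res$per_query
  # hits: D1 (dice 1.0) then D2 (dice 16/18); predicted {T1} u {T2,T3}
  expect_equal(row$NKT, 2)
  expect_equal(row$NPT, 3)
  expect_equal(c(row$TP, row$FP, row$FN, row$TN), c(2, 1, 0, 1))
  expect_equal(row$accuracy, 3 / 4)
  expect_equal(row$precision, 2 / 3)
  expect_equal(row$recall, 1)
  expect_equal(row$mcc, 2 / sqrt(12))
  expect_equal(res$universe_size, 4)
  # aggregate over one query mirrors the row
  expect_equal(res$aggregate$avPrecision, 2 / 3)
  expect_equal(res$aggregate$avNPT, 3)
})

test_that("queries without fingerprints are excluded with reasons, not averaged", {
  map <- map_from_pairs(data.frame(
    molecule_id = c("Q1", "Q2", "D1"), target_id = c("T1", "T1", "T1"),
    stringsAsFactors = FALSE
  ))
  fps <- fp_db(list(Q1 = make_fp(1:5), Q2 = fp_unavailable("multi_component"),
                    D1 = make_fp(1:5)))
  part <- benchmark_partition(map, c("Q1", "Q2"), "D1")
  suppressMessages(res <- run_benchmark(part, fps, map, k = 1))
  expect_equal(res$per_query$query_id, "Q1")
  expect_equal(res$unevaluable$query_id, "Q2")
  expect_equal(res$aggregate$n_queries, 1)
  expect_equal(res$aggregate$avRecall, 1)
})

test_that("avRecall and avNPT are non-decreasing in k", {
  cfg <- synthetic_config(n_series = 15, molecules_per_series = 5,
                          bitflip_noise = 0.05, activity_range = c(1, 1e4),
                          seed = 31)
  db <- generate_database(cfg)
  map <- apply_selection_filters(
    load_activity_table(write_records_csv_from_dialect(db$activity)),
    filter_criteria(threshold_nM = 1e4))
  part <- benchmark_partition(map, db$queries)
  prev_recall <- -1; prev_npt <- -1
  for (k in c(1, 5, 10, 15)) {
    res <- run_benchmark(part, db$fingerprints, map, k)
    expect_gte(res$aggregate$avRecall, prev_recall)
    expect_gte(res$aggregate$avNPT, prev_npt)
    prev_recall <- res$aggregate$avRecall
    prev_npt <- res$aggregate$avNPT
  }
})

test_that("neglected_targets is the coverage difference with its guards", {
  expect_equal(neglected_targets(3035, 917), 2118L)
  expect_equal(neglected_targets(2580, 1788), 792L)
  expect_equal(neglected_targets(1543, 1543), 0L)
  expect_error(neglected_targets(100, 200), "n_ligand_centric >= n_method")
  expect_error(neglected_targets(100, -1), "n_ligand_centric >= n_method")
})

test_that("coverage_table counts universes per method class against floor 1", {
  # 3 targets: T1 has 3 ligands, T2 has 2, T3 has 1
  pairs <- data.frame(
    molecule_id = c("M1", "M2", "M3", "M1", "M2", "M1"),
    target_id = c("T1", "T1", "T1", "T2", "T2", "T3"),
    stringsAsFactors = FALSE
  )
  recs <- do.call(rbind, Map(function(m, t) activity_row(m, t, 100),
                             pairs$molecule_id, pairs$target_id))
  cov <- coverage_table(recs, data.frame(min_ligands = c(1, 2, 3),
                                         threshold_nM = 10000))
  expect_equal(cov$n_targets_method, c(3L, 2L, 1L))
  expect_equal(cov$n_targets_ligand_centric, rep(3L, 3))
  expect_equal(cov$n_neglected, c(0L, 1L, 2L))
})

test_that("overlap_report names every confusion cell with its support", {
  w_map <- map_from_pairs(data.frame(
    molecule_id = c("D1", "D1", "Q1"), target_id = c("T1", "T2", "T1"),
    stringsAsFactors = FALSE
  ))
  db <- fp_db(list(D1 = make_fp(1:5)))
  p <- predict_targets("Q1", make_fp(1:5), db, w_map, 1)

  # worked-example cardinalities: NKT=67, NPT=9, overlap 8
  known67 <- sprintf("K%02d", 1:67)
  pred9 <- structure(p, class = "query_prediction")
  pred9$predicted_targets <- c(known67[1:8], "NEW1")
  rep <- overlap_report(pred9, known67)
  expect_equal(c(rep$NKT, rep$NPT), c(67, 9))
  expect_equal(lengths(rep[c("tp", "fp", "fn")]), c(tp = 8L, fp = 1L, fn = 59L))

  # selective-drug flavor: NKT=3, NPT=21, one TP
  pred21 <- pred9
  pred21$predicted_targets <- c("K01", sprintf("NEW%02d", 1:20))
  rep <- overlap_report(pred21, known67[1:3])
  expect_equal(length(rep$tp), 1)
  expect_equal(length(rep$fp), 20)

  # empty prediction: everything known is missed
  pred0 <- pred9
  pred0$predicted_targets <- character()
  rep <- overlap_report(pred0, c("T1", "T9"))
  expect_equal(rep$fn, c("T1", "T9"))
  expect_equal(rep$tp, character())
  expect_equal(rep$fp, character())
})
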