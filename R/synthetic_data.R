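#' Configuration for the synthetic chemogenomics generator
#'
#' The generator emulates the structure of curated bioactivity data that the
#' pipeline runs on: clusters of chemically similar molecules ("series")
#' sharing a target annotation set, a heavy-tailed number-of-targets
#' distribution with promiscuous outliers, potencies spanning nM to 100 uM,
#' and an observation mask that can record drug-like queries more deeply
#' than ordinary database molecules.
#'
#' @param n_series number of chemical series.
#' @param molecules_per_series members per series (>= 2 so every query has a
#'   series mate in the database).
#' @param prototype_on_rate Bernoulli rate for the on-bits of each series
#'   prototype fingerprint (166-key fingerprints of drug-like molecules
#'   typically light up a quarter of the keys).
#' @param bitflip_noise per-bit flip probability applied to each member's
#'   copy of the prototype — within-series structural variation.
#' @param targets_per_series list(min, lambda): a series carries
#'   `min + Poisson(lambda)` targets of its own.
#' @param promiscuity_tail list(prob, size, mu, max_extra): with probability
#'   `prob` a molecule is promiscuous and gains `NegBinom(size, mu)` extra
#'   targets (capped at `max_extra`) drawn from other series' targets — the
#'   small-size negative binomial produces the heavy upper tail of
#'   multi-hundred-target outliers seen in real data.
#' @param activity_range log-uniform potency bounds in nM.
#' @param observation_rate_db,observation_rate_query probability that a true
#'   (molecule, target) pair is actually recorded, by role.
#' @param disqualified_fraction fraction of extra deliberately disqualified
#'   measurement rows (censored relation, wrong units, low confidence, ...)
#'   appended to exercise the qualification filters.
#' @param n_queries how many series contribute their first member as a
#'   designated query (default: all).
#' @param seed master seed; every stage draws from its own substream so
#'   changing one stage's draw count does not perturb the others.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_series = 60,
                             molecules_per_series = 8,
                             prototype_on_rate = 0.25,
                             bitflip_noise = 0.02,
                             targets_per_series = list(min = 1, lambda = 2),
                             promiscuity_tail = list(prob = 0.05, size = 0.3,
                                                     mu = 20, max_extra = 250),
                             activity_range = c(1, 1e5),
                             observation_rate_db = 1.0,
                             observation_rate_query = 1.0,
                             disqualified_fraction = 0,
                             n_queries = n_series,
                             seed = 1L) {
  assert_scalar_number(n_series, "n_series", positive = TRUE)
  assert_scalar_number(molecules_per_series, "molecules_per_series", positive = TRUE)
  for (p in c(prototype_on_rate, bitflip_noise, observation_rate_db,
              observation_rate_query, disqualified_fraction)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stopf("probabilities must lie in [0, 1]", class = "tfbench_config_error")
    }
  }
  if (length(activity_range) != 2L || any(activity_range <= 0) ||
      activity_range[1] > activity_range[2]) {
    stopf("`activity_range` must be positive increasing bounds in nM",
          class = "tfbench_config_error")
  }
  if (n_queries > n_series) {
    stopf("`n_queries` cannot exceed `n_series`", class = "tfbench_config_error")
  }
  if (n_queries >= 1 && molecules_per_series < 2) {
    stopf("molecules_per_series must be >= 2 when series queries are evaluated",
          class = "tfbench_config_error")
  }
  structure(list(n_series = as.integer(n_series),
                 molecules_per_series = as.integer(molecules_per_series),
                 fingerprint_length = 166L,
                 prototype_on_rate = prototype_on_rate,
                 bitflip_noise = bitflip_noise,
                 targets_per_series = targets_per_series,
                 promiscuity_tail = promiscuity_tail,
                 activity_range = as.numeric(activity_range),
                 observation_rate_db = observation_rate_db,
                 observation_rate_query = observation_rate_query,
                 disqualified_fraction = disqualified_fraction,
                 n_queries = as.integer(n_queries),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

disqualify_row <- function(row) {
  choice <- sample(c("relation", "units", "confidence", "assay", "type"), 1L)
  switch(choice,
         relation = row$standard_relation <- ">",
         units = row$standard_units <- "ug.mL-1",
         confidence = row$confidence_score <- 8L,
         assay = row$assay_type <- "F",
         type = row$standard_type <- "Inhibition")
  row
}

#' Generate a synthetic chemogenomics database with ground truth
#'
#' Each series gets a prototype fingerprint; members are noisy copies and
#' share the series target set; promiscuous molecules gain cross-series
#' targets; every true pair receives a log-uniform potency and qualifying
#' measurement metadata; finally the observation mask is applied with
#' role-dependent rates ([bias_mask()]). Fully reproducible from the seed.
#'
#' Synthetic molecules carry fingerprints directly — no SMILES — so the
#' generator needs no chemistry toolkit; downstream stages consume them
#' through the same [fp_db()] interface as real data.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_db`: `config`, `series` (data.frame molecule_id /
#'   series_id / role), `truth` (named list molecule -> sorted true target
#'   ids), `fingerprints` ([fp_db()]), `activity_full` (unmasked record
#'   table in the default [activity_dialect()] column names),
#'   `activity` (masked table actually observed), `queries` (character).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ns <- config$n_series
  ms <- config$molecules_per_series
  n_mol <- ns * ms
  series_id <- rep(sprintf("SER%04d", seq_len(ns)), each = ms)
  molecule_id <- sprintf("MOL%06d", seq_len(n_mol))
  queries <- molecule_id[(seq_len(config$n_queries) - 1L) * ms + 1L]

  # stage 1: series target sets (disjoint between series; promiscuity links them)
  sizes <- with_seed(substream_seed(config$seed, 1L),
                     config$targets_per_series$min +
                       rpois(ns, config$targets_per_series$lambda))
  total_targets <- sum(sizes)
  target_pool <- sprintf("TGT%05d", seq_len(total_targets))
  series_targets <- split(target_pool, rep(seq_len(ns), times = sizes))

  # stage 2: fingerprints — prototype per series, per-bit flips per member
  fps <- with_seed(substream_seed(config$seed, 2L), {
    protos <- matrix(rbinom(ns * 166L, 1L, config$prototype_on_rate),
                     nrow = ns, ncol = 166L)
    bits <- protos[rep(seq_len(ns), each = ms), , drop = FALSE]
    if (config$bitflip_noise > 0) {
      flips <- matrix(rbinom(n_mol * 166L, 1L, config$bitflip_noise),
                      nrow = n_mol, ncol = 166L)
      bits <- (bits + flips) %% 2L
    }
    bits
  })
  fp_list <- lapply(seq_len(n_mol), function(i) fingerprint(fps[i, ]))
  names(fp_list) <- molecule_id

  # stage 3: promiscuity — heavy-tailed extra targets from other series
  truth <- with_seed(substream_seed(config$seed, 3L), {
    tail <- config$promiscuity_tail
    lapply(seq_len(n_mol), function(i) {
      s <- (i - 1L) %/% ms + 1L
      own <- series_targets[[s]]
      extra <- character()
      if (tail$prob > 0 && runif(1) < tail$prob) {
        others <- target_pool[!(target_pool %in% own)]
        n_extra <- min(rnbinom(1L, size = tail$size, mu = tail$mu),
                       tail$max_extra, length(others))
        if (n_extra > 0) extra <- sample(others, n_extra)
      }
      sort(unique(c(own, extra)))
    })
  })
  names(truth) <- molecule_id

  # stage 4: one qualifying measurement row per true pair
  pair_mol <- rep(molecule_id, times = lengths(truth))
  pair_tgt <- unlist(truth, use.names = FALSE)
  n_pairs <- length(pair_mol)
  activity_full <- with_seed(substream_seed(config$seed, 4L), {
    lo <- log10(config$activity_range[1])
    hi <- log10(config$activity_range[2])
    tab <- data.frame(
      molecule_chembl_id = pair_mol,
      target_chembl_id = pair_tgt,
      target_type = "SINGLE PROTEIN",
      standard_type = sample(c("EC50", "Ki", "Kd", "IC50"), n_pairs, replace = TRUE),
      standard_relation = "=",
      standard_value = signif(10^runif(n_pairs, lo, hi), 6),
      standard_units = "nM",
      assay_type = "B",
      confidence_score = 9L,
      stringsAsFactors = FALSE
    )
    n_bad <- round(config$disqualified_fraction * n_pairs)
    if (n_bad > 0) {
      idx <- sample(n_pairs, n_bad, replace = TRUE)
      bad <- do.call(rbind, lapply(idx, function(i) disqualify_row(tab[i, ])))
      tab <- rbind(tab, bad)
      rownames(tab) <- NULL
    }
    tab
  })

  db <- structure(list(config = config,
                       series = data.frame(molecule_id = molecule_id,
                                           series_id = series_id,
                                           role = ifelse(molecule_id %in% queries,
                                                         "query", "database"),
                                           stringsAsFactors = FALSE),
                       truth = truth,
                       fingerprints = fp_db(fp_list),
                       activity_full = activity_full,
                       activity = activity_full,
                       queries = queries),
                  class = "synthetic_db")
  db$activity <- bias_mask(db, queries,
                           rate_query = config$observation_rate_query,
                           rate_db = config$observation_rate_db,
                           seed = substream_seed(config$seed, 5L))
  db
}

#' @export
print.synthetic_db <- function(x, ...) {
  cat(sprintf("<synthetic db: %d series x %d molecules, %d targets, %d/%d observed rows, %d queries>\n",
              x$config$n_series, x$config$molecules_per_series,
              length(unique(unlist(x$truth))),
              nrow(x$activity), nrow(x$activity_full), length(x$queries)))
  invisible(x)
}

#' Apply an observation-bias mask to the true activity table
#'
#' Real bioactivity databases record only the pairs someone tested, and
#' drug-like molecules get tested against far more targets than ordinary
#' series compounds. The mask keeps each true (molecule, target) pair
#' independently, with a rate chosen by the molecule's role. Draws are keyed
#' to the fixed pair order, so for the same seed the table observed at a
#' lower rate is a subset of the table at a higher rate.
#'
#' @param truth a `synthetic_db` (its unmasked `activity_full` is masked).
#' @param query_ids molecules in the "query" role.
#' @param rate_query,rate_db retention probabilities in \[0, 1\].
#' @param seed integer.
#' @return the observed activity table (subset of `truth$activity_full`).
#' @export
bias_mask <- function(truth, query_ids, rate_query, rate_db, seed) {
  stopifnot(inherits(truth, "synthetic_db"))
  for (r in c(rate_query, rate_db)) {
    if (!is.numeric(r) || r < 0 || r > 1) {
      stopf("observation rates must lie in [0, 1]", class = "tfbench_config_error")
    }
  }
  tab <- truth$activity_full
  pair_key <- paste(tab$molecule_chembl_id, tab$target_chembl_id, sep = "\r")
  pairs <- sort(unique(pair_key))
  u <- with_seed(seed, runif(length(pairs)))
  names(u) <- pairs
  rate <- ifelse(tab$molecule_chembl_id %in% query_ids, rate_query, rate_db)
  keep <- u[pair_key] <= rate
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write synthetic artifacts as plain text
#'
#' `write_synthetic_activity()` emits the observed activity table in the
#' default dialect CSV; `write_truth_map()` the full pre-mask truth pairs as
#' TSV (for test assertions, not for the pipeline).
#'
#' @param db a `synthetic_db`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_synthetic_activity <- function(db, path) {
  stopifnot(inherits(db, "synthetic_db"))
  write.csv(db$activity, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_synthetic_activity
#' @export
write_truth_map <- function(db, path) {
  stopifnot(inherits(db, "synthetic_db"))
  writeLines(c("molecule_id\ttarget_id",
               paste(rep(names(db$truth), lengths(db$truth)),
                     unlist(db$truth, use.names = FALSE), sep = "\t")), path)
  invisible(path)
}
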