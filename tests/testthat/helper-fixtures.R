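# Shared fixture builders. Everything is generated in code; no binary data.

# fingerprint with the given on-bit positions
make_fp <- function(on = integer()) {
  bits <- integer(166)
  bits[on] <- 1L
  fingerprint(bits)
}

random_fp <- function(rate = 0.25) {
  fingerprint(stats::rbinom(166, 1, rate))
}

# one canonical activity record row; defaults qualify under default criteria
activity_row <- function(molecule, target, value,
                         type = "IC50", relation = "=", units = "nM",
                         assay = "B", confidence = 9L,
                         target_type = "SINGLE PROTEIN") {
  data.frame(molecule_id = molecule, target_id = target,
             target_type = target_type, activity_type = type,
             relation = relation, value = value, units = units,
             assay_type = assay, confidence = as.integer(confidence),
             stringsAsFactors = FALSE)
}

# the six-row toy table: one fully qualifying potent row, then one failure
# per filter dimension
toy_activity_records <- function() {
  rbind(
    activity_row("M1", "T1", 500),                       # qualifies at both thresholds
    activity_row("M1", "T2", 500, relation = ">"),       # censored relation
    activity_row("M2", "T3", 5000, type = "Ki"),         # qualifies at 10 uM only
    activity_row("M2", "T4", 500, type = "Inhibition"),  # wrong endpoint
    activity_row("M3", "T5", 500, confidence = 8L),      # low confidence
    activity_row("M3", "T6", 500, units = "ug.mL-1")     # wrong units
  )
}

# build a qualifying known-target map directly from (molecule, target) pairs
map_from_pairs <- function(pairs, criteria = filter_criteria()) {
  recs <- do.call(rbind, Map(function(m, t) activity_row(m, t, 100),
                             pairs$molecule_id, pairs$target_id))
  apply_selection_filters(recs, criteria)
}

# write canonical records as a CSV in the default dialect column names
write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  out <- data.frame(
    molecule_chembl_id = records$molecule_id,
    target_chembl_id = records$target_id,
    target_type = records$target_type,
    standard_type = records$activity_type,
    standard_relation = records$relation,
    standard_value = records$value,
    standard_units = records$units,
    assay_type = records$assay_type,
    confidence_score = records$confidence,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

# full independent re-evaluation of the selection filters: per-row boolean
# scan, then ligand-floor pruning. Used as the oracle for small tables.
oracle_filter_pairs <- function(records, criteria) {
  pass <- records$activity_type %in% criteria$allowed_activity_types &
    records$relation == criteria$required_relation &
    records$units == criteria$required_units &
    records$assay_type == criteria$required_assay_type &
    records$confidence == criteria$required_confidence &
    records$target_type == criteria$required_target_type &
    records$value <= criteria$threshold_nM
  pairs <- unique(records[pass, c("molecule_id", "target_id")])
  if (nrow(pairs)) {
    counts <- table(pairs$target_id)
    pairs <- pairs[pairs$target_id %in% names(counts)[counts >= criteria$min_ligands], ]
  }
  sort(paste(pairs$molecule_id, pairs$target_id))
}

# random canonical record table mixing qualifying and disqualified rows
random_records <- function(n, n_mol = 8, n_tgt = 6) {
  data.frame(
    molecule_id = sprintf("M%02d", sample(n_mol, n, replace = TRUE)),
    target_id = sprintf("T%02d", sample(n_tgt, n, replace = TRUE)),
    target_type = sample(c("SINGLE PROTEIN", "PROTEIN COMPLEX"), n, TRUE, c(.8, .2)),
    activity_type = sample(c("IC50", "Ki", "Kd", "EC50", "Inhibition"), n, TRUE),
    relation = sample(c("=", ">", "<"), n, TRUE, c(.8, .1, .1)),
    value = signif(10^stats::runif(n, 0, 5.5), 4),
    units = sample(c("nM", "ug.mL-1"), n, TRUE, c(.9, .1)),
    assay_type = sample(c("B", "F"), n, TRUE, c(.85, .15)),
    confidence = sample(c(9L, 8L), n, TRUE, c(.85, .15)),
    stringsAsFactors = FALSE
  )
}

# a synthetic world in the exact-transfer regime: no structural noise, full
# observation, potencies all within the threshold
exact_regime_config <- function(n_series = 20, molecules_per_series = 5, seed = 11) {
  synthetic_config(
    n_series = n_series, molecules_per_series = molecules_per_series,
    bitflip_noise = 0,
    promiscuity_tail = list(prob = 0, size = 0.3, mu = 20, max_extra = 250),
    activity_range = c(1, 1e4),
    seed = seed
  )
}

# records table of a synthetic db in canonical column names
synthetic_records <- function(db) {
  load_activity_table(write_records_csv_from_dialect(db$activity))
}

write_records_csv_from_dialect <- function(tab, path = tempfile(fileext = ".csv")) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  path
}

expect_same_sets <- function(a, b) {
  expect_setequal(as.character(a), as.character(b))
}
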