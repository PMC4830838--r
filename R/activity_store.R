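#' Qualification criteria for bioactivity measurements
#'
#' A measured (molecule, target) interaction only counts as a known target
#' when the measurement is a direct, high-confidence, single-protein binding
#' assay with a sufficiently potent dose-response value. These are the knobs:
#'
#' * `threshold_nM` — potency cutoff in nM; values at or below it qualify
#'   (1000 = 1 uM, 10000 = 10 uM are the conventional settings).
#' * `allowed_activity_types` — dose-response endpoints that qualify.
#' * `required_relation` — the measurement must be an exact value (`"="`),
#'   not a censored bound.
#' * `required_units`, `required_assay_type`, `required_confidence`,
#'   `required_target_type` — standardized units, binding ("B") assays,
#'   top curator confidence, and single-protein targets only.
#' * `min_ligands` — a target enters the universe only with at least this
#'   many distinct qualifying ligands; ligand-centric methods use 1,
#'   target-centric model classes need 5–40.
#'
#' @param threshold_nM positive potency cutoff in nM.
#' @param allowed_activity_types character vector of qualifying endpoints.
#' @param required_relation,required_units,required_assay_type character
#'   scalars.
#' @param required_confidence integer 0–9.
#' @param required_target_type character scalar.
#' @param min_ligands positive integer.
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(threshold_nM = 10000,
                            allowed_activity_types = c("EC50", "Ki", "Kd", "IC50"),
                            required_relation = "=",
                            required_units = "nM",
                            required_assay_type = "B",
                            required_confidence = 9L,
                            required_target_type = "SINGLE PROTEIN",
                            min_ligands = 1L) {
  assert_scalar_number(threshold_nM, "threshold_nM", positive = TRUE)
  assert_scalar_number(min_ligands, "min_ligands", positive = TRUE)
  if (min_ligands < 1 || min_ligands != as.integer(min_ligands)) {
    stopf("`min_ligands` must be a whole number >= 1", class = "tfbench_config_error")
  }
  structure(list(threshold_nM = as.numeric(threshold_nM),
                 allowed_activity_types = as.character(allowed_activity_types),
                 required_relation = required_relation,
                 required_units = required_units,
                 required_assay_type = required_assay_type,
                 required_confidence = as.integer(required_confidence),
                 required_target_type = required_target_type,
                 min_ligands = as.integer(min_ligands)),
            class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat(sprintf(
    "<filter criteria: %s, '%s' relation, %s, assay '%s', confidence %d, '%s', <= %g nM, min %d ligand(s)/target>\n",
    paste(x$allowed_activity_types, collapse = "/"), x$required_relation,
    x$required_units, x$required_assay_type, x$required_confidence,
    x$required_target_type, x$threshold_nM, x$min_ligands))
  invisible(x)
}

#' Column-name dialect for bioactivity tables
#'
#' Maps the canonical record fields onto the column names of a particular
#' file. The default mirrors standard ChEMBL-style field names.
#'
#' @param ... overrides, e.g. `value = "standard_value_nm"`.
#' @return named character vector: canonical field -> file column.
#' @export
activity_dialect <- function(...) {
  d <- c(molecule_id = "molecule_chembl_id",
         target_id = "target_chembl_id",
         target_type = "target_type",
         activity_type = "standard_type",
         relation = "standard_relation",
         value = "standard_value",
         units = "standard_units",
         assay_type = "assay_type",
         confidence = "confidence_score")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) stopf("unknown dialect field(s): %s", paste(bad, collapse = ", "),
                           class = "tfbench_config_error")
    d[names(over)] <- over
  }
  d
}

#' Load a bioactivity table
#'
#' Reads a CSV/TSV with one row per measurement and returns a normalized
#' record table. Rows whose value column cannot be parsed as a number are
#' dropped and counted — never silently. Categorical fields are
#' whitespace-trimmed; comparisons downstream are exact and case-sensitive.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @param dialect an [activity_dialect()] mapping.
#' @return a data.frame with canonical columns (`molecule_id`, `target_id`,
#'   `target_type`, `activity_type`, `relation`, `value`, `units`,
#'   `assay_type`, `confidence`) and a `load_report` attribute
#'   (`rows_read`, `rows_kept`, `rows_dropped`).
#' @export
load_activity_table <- function(path, dialect = activity_dialect()) {
  if (!file.exists(path)) stopf("activity table not found: %s", path, class = "tfbench_io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing)) {
    stopf("activity table is missing required column(s): %s",
          paste(missing, collapse = ", "), class = "tfbench_config_error")
  }
  rows_read <- nrow(raw)
  rec <- data.frame(
    molecule_id = trimws(raw[[dialect[["molecule_id"]]]]),
    target_id = trimws(raw[[dialect[["target_id"]]]]),
    target_type = trimws(raw[[dialect[["target_type"]]]]),
    activity_type = trimws(raw[[dialect[["activity_type"]]]]),
    relation = trimws(raw[[dialect[["relation"]]]]),
    value = suppressWarnings(as.numeric(raw[[dialect[["value"]]]])),
    units = trimws(raw[[dialect[["units"]]]]),
    assay_type = trimws(raw[[dialect[["assay_type"]]]]),
    confidence = suppressWarnings(as.integer(raw[[dialect[["confidence"]]]])),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(rec$value) & !is.na(rec$confidence) &
    nzchar(rec$molecule_id) & nzchar(rec$target_id)
  rec <- rec[ok, , drop = FALSE]
  rownames(rec) <- NULL
  report <- list(rows_read = rows_read, rows_kept = nrow(rec),
                 rows_dropped = rows_read - nrow(rec))
  tf_log(2, "loaded %d rows from %s (%d dropped as unparseable)",
         report$rows_kept, path, report$rows_dropped)
  attr(rec, "load_report") <- report
  rec
}

#' Build the known-target map from qualifying measurements
#'
#' A (molecule, target) pair is retained iff at least one of its
#' measurements passes every categorical filter AND its value is at or
#' below `threshold_nM`; targets with fewer than `min_ligands` distinct
#' retained ligands are then removed entirely, and molecules left with
#' empty target sets are dropped. The most permissive reading is used for
#' replicate measurements that disagree across the threshold: any single
#' qualifying measurement suffices.
#'
#' @param records a record table from [load_activity_table()] (or any
#'   data.frame with the canonical columns).
#' @param criteria a [filter_criteria()].
#' @return an object of class `known_target_map`: `forward` (named list
#'   molecule -> sorted target ids), `reverse` (target -> sorted molecule
#'   ids), `pairs` (two-column data.frame) and `criteria`. A `filter_report`
#'   attribute counts, per filter, the rows that fail it.
#' @export
apply_selection_filters <- function(records, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"))
  need <- c("molecule_id", "target_id", "target_type", "activity_type",
            "relation", "value", "units", "assay_type", "confidence")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stopf("records lack canonical column(s): %s", paste(missing, collapse = ", "),
          class = "tfbench_config_error")
  }
  n <- nrow(records)
  fail <- list(
    activity_type = !(records$activity_type %in% criteria$allowed_activity_types),
    relation = records$relation != criteria$required_relation,
    units = records$units != criteria$required_units,
    assay_type = records$assay_type != criteria$required_assay_type,
    confidence = records$confidence != criteria$required_confidence,
    target_type = records$target_type != criteria$required_target_type,
    threshold = !(records$value <= criteria$threshold_nM)
  )
  report <- c(list(rows_in = n), lapply(fail, sum))
  pass <- !Reduce(`|`, fail)
  pairs <- unique(records[pass, c("molecule_id", "target_id"), drop = FALSE])
  report$rows_passing <- sum(pass)
  report$pairs_before_min_ligands <- nrow(pairs)

  # prune targets below the ligand floor; molecules may then lose their sets
  if (nrow(pairs)) {
    lig_counts <- table(pairs$target_id)
    keep_t <- names(lig_counts)[lig_counts >= criteria$min_ligands]
    pairs <- pairs[pairs$target_id %in% keep_t, , drop = FALSE]
  }
  report$pairs_kept <- nrow(pairs)
  pairs <- pairs[order(pairs$molecule_id, pairs$target_id), , drop = FALSE]
  rownames(pairs) <- NULL

  forward <- lapply(split(pairs$target_id, pairs$molecule_id), sort)
  reverse <- lapply(split(pairs$molecule_id, pairs$target_id), sort)
  tf_log(2, "selection filters: %d rows in, %d qualifying, %d pairs kept (%d molecules, %d targets)",
         n, report$rows_passing, nrow(pairs), length(forward), length(reverse))
  structure(list(forward = forward, reverse = reverse, pairs = pairs,
                 criteria = criteria),
            class = "known_target_map", filter_report = report)
}

#' @export
print.known_target_map <- function(x, ...) {
  cat(sprintf("<known-target map: %d molecules, %d targets, %d pairs>\n",
              length(x$forward), length(x$reverse), nrow(x$pairs)))
  print(x$criteria)
  invisible(x)
}

#' Target universe at a ligand floor
#'
#' The set of targets with at least `min_ligands` distinct qualifying
#' ligands. Shrinks monotonically as the floor rises — the coverage gap
#' between ligand-centric (floor 1) and model-based method classes.
#'
#' @param map a `known_target_map`.
#' @param min_ligands positive integer floor; defaults to the map's own
#'   criteria.
#' @return sorted character vector of target ids.
#' @export
target_universe <- function(map, min_ligands = map$criteria$min_ligands) {
  stopifnot(inherits(map, "known_target_map"))
  assert_scalar_number(min_ligands, "min_ligands", positive = TRUE)
  counts <- lengths(map$reverse)
  sort(names(counts)[counts >= min_ligands])
}

#' Known targets of one molecule
#'
#' The molecule's qualifying target set under the map's criteria; its size
#' is the molecule's NKT (number of known targets). Absent molecules give
#' the empty set.
#'
#' @param map a `known_target_map`.
#' @param molecule_id molecule id.
#' @return sorted character vector (possibly empty).
#' @export
known_targets <- function(map, molecule_id) {
  stopifnot(inherits(map, "known_target_map"))
  map$forward[[molecule_id]] %||% character()
}

#' Serialize / read a known-target map
#'
#' The on-disk format is a `#`-prefixed JSON header line recording the
#' criteria, then tab-separated (molecule_id, target_id) pairs.
#'
#' @param map a `known_target_map`.
#' @param path output file.
#' @return `write_known_target_map()`: the path, invisibly.
#' @export
write_known_target_map <- function(map, path) {
  stopifnot(inherits(map, "known_target_map"))
  header <- paste0("#", jsonlite::toJSON(unclass(map$criteria), auto_unbox = TRUE))
  lines <- c(header, "molecule_id\ttarget_id",
             paste(map$pairs$molecule_id, map$pairs$target_id, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_known_target_map
#' @return `read_known_target_map()`: a `known_target_map`.
#' @export
read_known_target_map <- function(path) {
  if (!file.exists(path)) stopf("known-target map not found: %s", path, class = "tfbench_io_error")
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#")) {
    stopf("known-target map file lacks its JSON criteria header", class = "tfbench_io_error")
  }
  crit <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  criteria <- do.call(filter_criteria, crit)
  body <- lines[-(1:2)]
  pairs <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    data.frame(molecule_id = vapply(parts, `[`, character(1), 1),
               target_id = vapply(parts, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(molecule_id = character(), target_id = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(forward = lapply(split(pairs$target_id, pairs$molecule_id), sort),
                 reverse = lapply(split(pairs$molecule_id, pairs$target_id), sort),
                 pairs = pairs, criteria = criteria),
            class = "known_target_map")
}
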