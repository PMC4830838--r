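#' Predict targets of a query molecule by annotation transfer
#'
#' The ligand-centric baseline: rank every database molecule by Dice
#' similarity to the query, take the top `k` hits, and return the
#' deduplicated union of their known targets as the predicted target set.
#' The prediction is an unordered set (NPT = its size); per-target support
#' (which hits contributed, at what score) is retained for reporting only.
#'
#' @param query_id id of the query molecule; must not be part of `db` —
#'   benchmark partitions keep query and database molecules disjoint.
#' @param query_fp the query's `maccs_fp`, or an [fp_unavailable()] marker.
#' @param db an [fp_db()] of database molecules.
#' @param known_map a [apply_selection_filters()] map supplying targets for
#'   the hits.
#' @param k positive integer; number of hit molecules (never targets).
#' @return a `query_prediction`: `query_id`, `k`, `hits` (ranked data.frame),
#'   `predicted_targets` (sorted character), `support` (named list
#'   target -> data.frame(hit id, score)). If the query fingerprint is
#'   unavailable, a `query_exclusion` with the reason instead.
#' @export
predict_targets <- function(query_id, query_fp, db, known_map, k) {
  stopifnot(inherits(db, "fp_db"), inherits(known_map, "known_target_map"))
  if (!fp_available(query_fp)) {
    reason <- if (inherits(query_fp, "fp_unavailable")) query_fp$reason else "unavailable"
    tf_log(1, "query %s excluded: fingerprint %s", query_id, reason)
    return(structure(list(query_id = query_id, reason = reason),
                     class = "query_exclusion"))
  }
  if (query_id %in% db$ids) {
    stopf("query '%s' is also a database molecule; partitions must be disjoint", query_id)
  }
  hits <- top_k(rank_database(query_fp, db), k)
  target_sets <- lapply(hits$molecule_id, known_targets, map = known_map)
  predicted <- sort(unique(unlist(target_sets)))
  support <- lapply(stats::setNames(predicted, predicted), function(t) {
    sel <- vapply(target_sets, function(s) t %in% s, logical(1))
    data.frame(molecule_id = hits$molecule_id[sel], score = hits$score[sel],
               stringsAsFactors = FALSE)
  })
  structure(list(query_id = query_id, k = as.integer(k), hits = hits,
                 predicted_targets = predicted, support = support),
            class = "query_prediction")
}

#' @export
print.query_prediction <- function(x, ...) {
  cat(sprintf("<prediction for %s (k=%d): NPT=%d from %d hit(s)>\n",
              x$query_id, x$k, length(x$predicted_targets), nrow(x$hits)))
  invisible(x)
}

#' Predict targets for a batch of queries
#'
#' Stateless per-query application of [predict_targets()]; unevaluable
#' queries (no fingerprint) are collected separately, never imputed.
#'
#' @param queries named list of `maccs_fp` / `fp_unavailable`, one per query.
#' @param db,known_map,k as in [predict_targets()].
#' @return list with `predictions` (named list of `query_prediction`) and
#'   `excluded` (data.frame query_id/reason).
#' @export
batch_predict <- function(queries, db, known_map, k) {
  stopifnot(is.list(queries))
  if (length(queries) && is.null(names(queries))) stopf("`queries` must be a named list")
  out <- lapply(names(queries), function(qid) {
    predict_targets(qid, queries[[qid]], db, known_map, k)
  })
  names(out) <- names(queries)
  is_excl <- vapply(out, inherits, logical(1), "query_exclusion")
  excluded <- data.frame(
    query_id = names(out)[is_excl],
    reason = vapply(out[is_excl], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  list(predictions = out[!is_excl], excluded = excluded)
}

#' Write predictions as JSON lines
#'
#' One JSON object per query: id, k, hits with scores, predicted targets
#' with their supporting hit ids.
#'
#' @param predictions list of `query_prediction` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_predictions_jsonl <- function(predictions, path) {
  lines <- vapply(predictions, function(p) {
    jsonlite::toJSON(list(
      query_id = p$query_id, k = p$k,
      hits = p$hits[, c("molecule_id", "score", "rank")],
      predicted_targets = lapply(p$support, function(s) s$molecule_id)
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
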