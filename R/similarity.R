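#' Dice similarity between two fingerprints
#'
#' `2c / (a + b)` where `a` and `b` are the on-bit counts of the two
#' fingerprints and `c` the count of bits on in both. Two all-zero
#' fingerprints score 0, not 1: a molecule with no detected features should
#' not match everything.
#'
#' @param fpA,fpB `maccs_fp` objects.
#' @return a number in \[0, 1\].
#' @examples
#' a <- fingerprint(c(rep(1, 4), rep(0, 162)))
#' b <- fingerprint(c(rep(0, 1), rep(1, 6), rep(0, 159)))
#' dice_score(a, b)  # a=4, b=6, c=3 -> 0.6
#' @export
dice_score <- function(fpA, fpB) {
  if (!inherits(fpA, "maccs_fp") || !inherits(fpB, "maccs_fp")) {
    stopf("dice_score() needs two fingerprints of length 166")
  }
  a <- attr(fpA, "popcount")
  b <- attr(fpB, "popcount")
  if (a + b == 0L) return(0)
  2 * sum(unclass(fpA) & unclass(fpB)) / (a + b)
}

#' Rank database molecules by similarity to a query
#'
#' Scores every molecule in the database against the query with the Dice
#' coefficient and sorts descending. Ties are broken by ascending molecule
#' id so rankings are reproducible.
#'
#' @param query_fp a `maccs_fp`.
#' @param db an [fp_db()].
#' @return a data.frame of class `ranked_hits` with columns `molecule_id`,
#'   `score`, `rank` (1-based, contiguous).
#' @export
rank_database <- function(query_fp, db) {
  if (!fp_available(query_fp)) stopf("query fingerprint unavailable")
  stopifnot(inherits(db, "fp_db"))
  n <- length(db$ids)
  if (n == 0L) {
    return(structure(data.frame(molecule_id = character(), score = numeric(),
                                rank = integer(), stringsAsFactors = FALSE),
                     class = c("ranked_hits", "data.frame")))
  }
  qbits <- unclass(query_fp)
  a <- attr(query_fp, "popcount")
  shared <- as.vector(db$bits %*% qbits)
  denom <- a + db$popcounts
  score <- ifelse(denom == 0L, 0, 2 * shared / denom)
  ord <- order(-score, db$ids, method = "radix")
  structure(data.frame(molecule_id = db$ids[ord], score = score[ord],
                       rank = seq_len(n), stringsAsFactors = FALSE),
            class = c("ranked_hits", "data.frame"))
}

#' Keep the top k hits of a ranking
#'
#' @param ranked a `ranked_hits` data.frame from [rank_database()].
#' @param k positive integer; hits beyond the ranking length are simply not
#'   there, so the result has `min(k, nrow(ranked))` rows.
#' @return the first rows of `ranked`.
#' @export
top_k <- function(ranked, k) {
  assert_scalar_number(k, "k", positive = TRUE)
  if (k != as.integer(k)) stopf("`k` must be a whole number", class = "tfbench_config_error")
  head(ranked, as.integer(k))
}
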