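#' Structural fingerprints (166 binary keys)
#'
#' A fingerprint is a fixed-length binary vector of 166 predefined
#' substructural keys (the MACCS key dictionary). `fingerprint()` builds one
#' from a 0/1 vector; [compute_fingerprint()] derives them from SMILES via
#' RDKit. The on-bit count is cached because the Dice score only needs
#' popcounts and the shared-bit count.
#'
#' @param bits integer/logical vector of length 166 with values 0/1.
#' @return an object of class `maccs_fp`: an integer vector of length 166
#'   with a `popcount` attribute.
#' @examples
#' fp <- fingerprint(rep(c(1L, 0L), 83))
#' fp_popcount(fp)
#' @export
fingerprint <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != 166L || anyNA(bits) || any(bits != 0L & bits != 1L)) {
    stopf("a fingerprint is exactly 166 binary keys")
  }
  structure(bits, popcount = sum(bits), class = "maccs_fp")
}

#' Marker for molecules whose fingerprint cannot be generated
#'
#' Unparseable structures and multi-component mixtures do not raise errors;
#' they yield a first-class unavailability marker so batch pipelines can
#' report and skip them.
#'
#' @param reason short machine-readable reason string.
#' @return an object of class `fp_unavailable`.
#' @export
fp_unavailable <- function(reason = "unparseable") {
  structure(list(reason = reason), class = "fp_unavailable")
}

#' @rdname fp_unavailable
#' @param x object to test.
#' @return `fp_available()`: TRUE if `x` is a usable fingerprint.
#' @export
fp_available <- function(x) inherits(x, "maccs_fp")

#' @rdname fingerprint
#' @param fp a `maccs_fp`.
#' @export
fp_popcount <- function(fp) {
  stopifnot(inherits(fp, "maccs_fp"))
  attr(fp, "popcount")
}

#' @export
print.maccs_fp <- function(x, ...) {
  cat(sprintf("<166-key fingerprint, %d on-bits>\n", attr(x, "popcount")))
  invisible(x)
}

#' @export
print.fp_unavailable <- function(x, ...) {
  cat(sprintf("<fingerprint unavailable: %s>\n", x$reason))
  invisible(x)
}

# --- hex codec: 166 bits + 2 trailing zero pad = 168 bits = 42 hex chars,
#     MSB-first within each 4-bit chunk. Mirrors inst/python/maccs_keys.py.

#' Fingerprint hex codec
#'
#' Serializes 166 bits as 42 hexadecimal characters (two zero bits of
#' padding), the format used by the fingerprint cache.
#'
#' @param fp a `maccs_fp`.
#' @return `fp_to_hex()`: a 42-character string.
#' @export
fp_to_hex <- function(fp) {
  stopifnot(inherits(fp, "maccs_fp"))
  bits <- c(unclass(fp), 0L, 0L)
  nib <- bits[seq(1, 168, 4)] * 8L + bits[seq(2, 168, 4)] * 4L +
    bits[seq(3, 168, 4)] * 2L + bits[seq(4, 168, 4)]
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[nib + 1L], collapse = "")
}

#' @rdname fp_to_hex
#' @param hex a 42-character hexadecimal string.
#' @return `hex_to_fp()`: a `maccs_fp`.
#' @export
hex_to_fp <- function(hex) {
  hex <- tolower(trimws(hex))
  if (!grepl("^[0-9a-f]{42}$", hex)) {
    stopf("fingerprint hex encoding must be 42 hexadecimal characters")
  }
  nib <- match(strsplit(hex, "")[[1]],
               c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                 "a", "b", "c", "d", "e", "f")) - 1L
  bits <- as.integer(rbind(nib %/% 8L, (nib %/% 4L) %% 2L,
                           (nib %/% 2L) %% 2L, nib %% 2L))
  if (any(bits[167:168] != 0L)) {
    stopf("fingerprint hex encoding has non-zero padding bits")
  }
  fingerprint(bits[1:166])
}

# --- RDKit bridge ----------------------------------------------------------

python_binary <- function() {
  getOption("tfbench.python", Sys.getenv("TFBENCH_PYTHON", "python"))
}

maccs_script <- function() {
  p <- system.file("python", "maccs_keys.py", package = "tfbench")
  if (!nzchar(p)) stopf("bundled maccs_keys.py not found; is tfbench installed?")
  p
}

run_maccs_helper <- function(mode, path, extra = character()) {
  out <- suppressWarnings(
    system2(python_binary(), c(shQuote(maccs_script()), mode, shQuote(path), extra),
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stopf("fingerprint helper failed (python exit status %d)", status)
  }
  out
}

parse_helper_lines <- function(lines) {
  res <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    res[[parts[1]]] <- if (parts[2] == "NA") {
      fp_unavailable(if (length(parts) >= 3L) parts[3] else "unparseable")
    } else {
      hex_to_fp(parts[2])
    }
  }
  res
}

#' Compute 166-key fingerprints from SMILES
#'
#' Runs the bundled RDKit helper in a `python` subprocess (the toolkit that
#' defines the canonical 166-key dictionary). Unparseable strings and
#' dot-disconnected mixtures yield [fp_unavailable()] markers, never errors.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional names for the result; defaults to the SMILES
#'   themselves (made unique).
#' @return a named list, each element a `maccs_fp` or an `fp_unavailable`.
#'   For a single unnamed SMILES, the bare element.
#' @examples
#' \dontrun{
#' compute_fingerprint("CCO")
#' }
#' @export
compute_fingerprint <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles))
  scalar <- length(smiles) == 1L && is.null(ids)
  if (is.null(ids)) ids <- make.unique(smiles)
  if (length(ids) != length(smiles)) stopf("`ids` must match `smiles` in length")
  if (length(smiles) == 0L) return(stats::setNames(list(), character()))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(paste(ids, smiles, sep = "\t"), tmp)
  res <- parse_helper_lines(run_maccs_helper("smiles", tmp))
  # helper drops nothing silently: anything it did not answer is unavailable
  missing <- setdiff(ids, names(res))
  for (m in missing) res[[m]] <- fp_unavailable("no_helper_output")
  res <- res[ids]
  if (scalar) res[[1]] else res
}

#' Read molecule structures and fingerprint them
#'
#' `read_smiles_fingerprints()` reads a two-column `id<TAB>smiles` file;
#' `read_sdf_fingerprints()` reads an SDF, taking ids from `id_property`
#' or the molecule title.
#'
#' @param path input file.
#' @param id_property SDF property holding the molecule id (optional).
#' @return a named list of `maccs_fp` / `fp_unavailable`, as
#'   [compute_fingerprint()].
#' @export
read_smiles_fingerprints <- function(path) {
  if (!file.exists(path)) stopf("structure file not found: %s", path, class = "tfbench_io_error")
  parse_helper_lines(run_maccs_helper("smiles", path))
}

#' @rdname read_smiles_fingerprints
#' @export
read_sdf_fingerprints <- function(path, id_property = NULL) {
  if (!file.exists(path)) stopf("structure file not found: %s", path, class = "tfbench_io_error")
  parse_helper_lines(run_maccs_helper("sdf", path, extra = if (!is.null(id_property)) shQuote(id_property)))
}

# --- fingerprint database --------------------------------------------------

#' Fingerprint database
#'
#' A compact container for many fingerprints: an n x 166 integer matrix with
#' molecule ids as row keys. Unavailable fingerprints are excluded (and
#' recorded) — they cannot take part in a similarity search.
#'
#' @param fps named list of `maccs_fp` / `fp_unavailable` objects.
#' @return an object of class `fp_db` with elements `ids` (character),
#'   `bits` (integer matrix), `popcounts` (integer vector) and `excluded`
#'   (data.frame of id/reason).
#' @export
fp_db <- function(fps) {
  stopifnot(is.list(fps))
  if (length(fps) && is.null(names(fps))) stopf("`fps` must be a named list")
  ok <- vapply(fps, fp_available, logical(1))
  excluded <- data.frame(
    molecule_id = names(fps)[!ok],
    reason = vapply(fps[!ok], function(x) x$reason %||% "unavailable", character(1)),
    stringsAsFactors = FALSE
  )
  keep <- fps[ok]
  bits <- if (length(keep)) {
    do.call(rbind, lapply(keep, unclass))
  } else {
    matrix(integer(), nrow = 0, ncol = 166)
  }
  rownames(bits) <- names(keep)
  structure(list(ids = names(keep) %||% character(), bits = bits,
                 popcounts = as.integer(rowSums(bits)), excluded = excluded),
            class = "fp_db")
}

#' @export
length.fp_db <- function(x) length(x$ids)

#' @export
print.fp_db <- function(x, ...) {
  cat(sprintf("<fingerprint db: %d molecules, %d excluded>\n",
              length(x$ids), nrow(x$excluded)))
  invisible(x)
}

#' Subset a fingerprint database by molecule id
#' @param db an `fp_db`.
#' @param ids molecule ids to keep (silently drops ids not present).
#' @return an `fp_db`.
#' @export
fp_db_subset <- function(db, ids) {
  stopifnot(inherits(db, "fp_db"))
  keep <- db$ids %in% ids
  structure(list(ids = db$ids[keep],
                 bits = db$bits[keep, , drop = FALSE],
                 popcounts = db$popcounts[keep],
                 excluded = db$excluded),
            class = "fp_db")
}

#' Fetch one fingerprint from a database
#' @param db an `fp_db`.
#' @param id molecule id.
#' @return a `maccs_fp`, or `fp_unavailable` if absent/excluded.
#' @export
fp_db_get <- function(db, id) {
  i <- match(id, db$ids)
  if (is.na(i)) {
    reason <- if (id %in% db$excluded$molecule_id) {
      db$excluded$reason[match(id, db$excluded$molecule_id)]
    } else "not_in_database"
    return(fp_unavailable(reason))
  }
  fingerprint(db$bits[i, ])
}

#' Fingerprint cache file
#'
#' Tab-separated `id<TAB>hex42` (plus a third `reason` column for recorded
#' unavailable molecules). Reading a cache skips structure parsing entirely.
#'
#' @param db an `fp_db`.
#' @param path file path.
#' @return `write_fp_cache()`: the path, invisibly.
#' @export
write_fp_cache <- function(db, path) {
  stopifnot(inherits(db, "fp_db"))
  lines <- character()
  if (length(db$ids)) {
    hex <- vapply(seq_along(db$ids), function(i) fp_to_hex(fingerprint(db$bits[i, ])),
                  character(1))
    lines <- paste(db$ids, hex, sep = "\t")
  }
  if (nrow(db$excluded)) {
    lines <- c(lines, paste(db$excluded$molecule_id, "NA", db$excluded$reason, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fp_cache
#' @return `read_fp_cache()`: an `fp_db`.
#' @export
read_fp_cache <- function(path) {
  if (!file.exists(path)) stopf("fingerprint cache not found: %s", path, class = "tfbench_io_error")
  fp_db(parse_helper_lines(readLines(path)))
}
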