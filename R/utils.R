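#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rbinom rnbinom rpois runif median
#' @importFrom utils read.delim write.csv head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls never perturb the
#' caller's RNG stream. All randomness in tfbench flows through explicit
#' seeds via this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage substream seeds: changing one stage's draw count
# must not perturb other stages. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + stage * 1013904223) %% 2147483647)
}

stopf <- function(fmt, ..., class = "tfbench_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single number", name, class = "tfbench_config_error")
  }
  if (positive && x <= 0) {
    stopf("`%s` must be positive", name, class = "tfbench_config_error")
  }
  invisible(x)
}

#' Logging level for tfbench messages
#'
#' Messages go to stderr via [message()]. Levels: 0 quiet, 1 info, 2 debug.
#' Controlled by `options(tfbench.verbose = )`.
#' @param level numeric level of the message.
#' @param fmt,... sprintf-style message.
#' @return invisibly, NULL.
#' @keywords internal
tf_log <- function(level, fmt, ...) {
  if (getOption("tfbench.verbose", 1L) >= level) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
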