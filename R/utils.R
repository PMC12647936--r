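#' @keywords internal
"_PACKAGE"

MODALITIES <- c("exon", "mrna", "mirna", "methylation", "fused")
EXPRESSION_MODALITIES <- c("exon", "mrna", "mirna")

# Tokens treated as missing on input (case-insensitive).
NA_TOKENS <- c("na", "nan", "")

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

#' Derive a stage-specific seed from a run seed
#'
#' One run seed fans out to per-stage seeds so stages are independently
#' reproducible. The derivation hashes the stage name into [0, 2^31 - 2].
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 131 + h) %% 2147480009)
}

stop_masegc <- function(kind, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("masegc_", kind), "masegc_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
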