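#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rpois runif pnorm phyper sd setNames
#' @importFrom utils read.delim write.table head
#' @importFrom methods as
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are pure functions of
# (config, seed) and never perturb the session stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage substream: a distinct, reproducible seed for each
# named stage of a simulation, derived from one master seed.  Kept strictly
# inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  stages <- c(ppi = 1L, truth = 2L, pulldowns = 3L, disease = 4L,
              nulls = 5L, misc = 6L)
  k <- stages[[stage]]
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483563) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}
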