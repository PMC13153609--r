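#' @keywords internal
"_PACKAGE"

## Well indexing convention used throughout the package: grids are R matrices
## with [row, col] = [y, x], row 1 at the top-left of the section.  When wells
## are serialized (contour CSVs, mask files) indices are written 0-based,
## row-major, origin top-left.

# Fixed per-stage offsets for fanning one master seed out to sub-seeds.
# Adding a stage never perturbs the randomness of earlier stages.
.stage_offsets <- c(
  phantom    = 11L,
  proteome   = 23L,
  abundance  = 37L,
  imaging    = 53L,   # + layer index is added per layer
  stochastic = 71L
)

#' Derive a deterministic sub-seed from a master seed
#'
#' Sub-seeds are computed by fixed integer arithmetic so that the random
#' streams of individual pipeline stages are independent of how many stages
#' run, and adding a stage never reshuffles earlier ones.
#'
#' @param master master seed (single integer).
#' @param stage one of `"phantom"`, `"proteome"`, `"abundance"`,
#'   `"imaging"`, `"stochastic"`.
#' @param k extra offset (e.g. layer index) within a stage.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, k = 0L) {
  stopifnot(length(master) == 1L, is.finite(master))
  if (!stage %in% names(.stage_offsets)) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  off <- .stage_offsets[[stage]]
  as.integer(((abs(as.numeric(master)) %% 1000003) * 1009 +
                off * 9973 + as.numeric(k)) %% 2147483647)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# scalar validators
.check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(name, " must be a single finite number in [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  invisible(x)
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}
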