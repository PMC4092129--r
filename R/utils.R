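#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that
# every generator is a pure function of (parameters, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

#' Derive a stage sub-seed from a master seed
#'
#' Stable string hash so that inserting new pipeline stages does not
#' reshuffle the seeds of existing ones.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- as.double(utf8ToInt(stage))
  acc <- as.double(master) %% 2147483647
  for (v in h) acc <- (acc * 31 + v) %% 2147483647
  as.integer(acc)
}

# Round-half-up at `digits` decimals (base round() is round-half-even,
# which does not reproduce printed accuracy tables).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Truncate toward zero at `digits` decimals.
trunc_digits <- function(x, digits = 3L) {
  p <- 10^digits
  trunc(x * p) / p
}

stop_gyrospec <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gyrospec_error")))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
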