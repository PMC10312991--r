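# Shared numeric helpers.

#' Round half away from zero
#'
#' Base R rounds half to even; printed screening reports round half up
#' (e.g. 0.625 -> 0.63 in the standard two-fold dose ladder, and cascade
#' percentages such as 10.05 -> 10.1). This helper implements conventional
#' half-up rounding for nonnegative inputs.
#'
#' @param x numeric vector (nonnegative).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Consistency constant for MAD -> SD under normality.
MAD_SCALE <- 1.4826

#' Median absolute deviation scaled to the normal SD
#'
#' @param x numeric vector.
#' @return 1.4826 * median(|x - median(x)|).
#' @export
mad_sd <- function(x) {
  MAD_SCALE * stats::median(abs(x - stats::median(x)))
}

# Run `expr` under a deterministic RNG stream derived from `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# funnel through this so that seeds are explicit and global state untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index; stays below 2^31.
child_seed <- function(seed, index) {
  (as.integer(seed) * 7919L + as.integer(index) * 104729L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tgn <- function(class, msg, ...) {
  stop(structure(class = c(class, "tgnscreen_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
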