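#' @keywords internal
#' @useDynLib vdepeeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# The four design dimensions, in canonical order.
VDEPS <- c("colour", "balance", "movement", "light")

# Human-readable class labels per dimension (class 1, class 2).
VDEP_CLASS_NAMES <- list(
  colour   = c("cold", "warm"),
  balance  = c("asymmetrical", "symmetrical"),
  movement = c("fast", "slow"),
  light    = c("bright", "dark")
)

EEG_BAND_NAMES <- c("delta", "theta", "alpha", "beta", "gamma")

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library functions never perturb user seeds.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying within
# the 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("%s must be a probability in [0, 1], got %s", what,
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stopf("%s must be an integer >= %d", what, min)
  }
  invisible(as.integer(x))
}
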