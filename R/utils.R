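# Internal helpers: seeded evaluation, seed derivation, small validators.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the R random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards so seeded stages never disturb each other.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named seed stream from a master seed
#'
#' One master seed feeds independent, named streams (walks, skip-gram
#' initialization, fold partitions, ...) so that each stage is individually
#' reproducible.  The derivation is a fixed affine hash kept below 2^31.
#'
#' @param seed master seed (integer).
#' @param stream character stream name, e.g. `"walks"`.
#' @return a positive integer seed.
#' @export
#' @examples
#' derive_seed(42, "walks")
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 69069 + h * 7919 + 1
  as.integer(s %% 2147483629) + 1L
}

# Wrap phase differences into (-pi, pi].  atan2 keeps the boundary at +pi,
# which pins the sign convention for the phase-lag index.
wrap_phase <- function(x) atan2(sin(x), cos(x))

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x < min || x != as.integer(x)) {
    stop_param("`%s` must be an integer >= %d (got %s)", name, min,
               paste(format(x), collapse = ", "))
  }
  as.integer(x)
}

# Format a numeric for text artifacts: locale-independent, round-trips
# doubles through 1e-9 comfortably, and is byte-stable across runs.
fmt_num <- function(x) {
  out <- vapply(x, function(v) formatC(v, format = "g", digits = 15), "")
  sub("^-0$", "0", out)
}
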