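# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package internals never disturb
# user-level reproducibility.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Derive a substream seed from a base seed and a counter, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 1000003 * 2011 + as.double(counter)) %%
               2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  if (integer && x != round(x))
    stop_config(field, "must be an integer")
  if (x < lower) stop_config(field, sprintf("must be >= %s", lower))
  if (x > upper) stop_config(field, sprintf("must be <= %s", upper))
  invisible(x)
}

# 8-bit image sanity check: numeric array, integral values in [0, 255].
check_uint8 <- function(x, what = "image") {
  if (!is.numeric(x))
    stop(sprintf("%s must be numeric 8-bit data", what), call. = FALSE)
  r <- range(x)
  if (r[1] < 0 || r[2] > 255 || any(x != round(x)))
    stop(sprintf("%s must hold integer values in [0, 255] (8-bit)", what),
         call. = FALSE)
  invisible(x)
}

check_rgb_array <- function(x, what = "image") {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop(sprintf("%s must be a height x width x 3 array", what),
         call. = FALSE)
  invisible(x)
}
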