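# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Evaluate `code` under a deterministic RNG state without touching the
# caller's global RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_input("`seed` must be a single finite number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(abs(seed) %% 2147483646))
  force(code)
}

# Derive a stage seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * as.double(offset)) %% 2147483647)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop_input("`", name, "` must be a single integer >= ", min)
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok)
    stop_input("`", name, "` must be a single number in [", lower, ", ",
               upper, "]")
  as.numeric(x)
}

assert_prob <- function(x, name, include_one = TRUE) {
  upper <- if (include_one) 1 else 1 - .Machine$double.eps
  assert_number(x, name, lower = 0, upper = upper)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_input(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  invisible(df)
}
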