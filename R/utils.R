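# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive stable child seeds from one parent seed so pipeline stages are
# individually rerunnable. Offsets are fixed per stage name.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(
    simulate = 11L, distance = 23L, kscan = 37L, dapc = 41L,
    amova = 53L, temporal = 67L, bootstrap = 71L, ascore = 83L
  )
  off <- offsets[[stage]]
  (as.integer(seed) * 97L + off) %% 2147483629L
}

assert_scalar_prop <- function(x, name, closed_top = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 &&
    (if (closed_top) x <= 1 else x < 1)
  if (!ok) abort(sprintf("`%s` must be a single proportion in (0, 1%s]",
                         name, if (closed_top) "" else ")"))
  invisible(x)
}

# Modal value of an integer vector; ties broken toward the smallest value.
modal_min <- function(x) {
  tab <- table(x)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}
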