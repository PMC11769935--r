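#' @keywords internal
"_PACKAGE"

# Deterministic derivation of stage seeds from one master seed.
# Keeps every derived value in [1, 2^31 - 2] so it is a valid R integer seed.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 2147483629
  as.integer((abs(master) + h) %% 2147483629 + 1)
}

# Run `expr` under a locally-seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_arg("`%s` must be a single number in [%s, %s]", name,
             format(lower), format(upper))
  x
}
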