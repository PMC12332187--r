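#' Derive a child seed from arbitrary components
#'
#' Every stochastic operation in the simulator derives its own seed from a
#' master seed plus an entity identifier, so whole pipelines are bit-identical
#' given the master seed while independent entities get decorrelated streams.
#' The hash is a simple polynomial string hash over the concatenated
#' components, reduced modulo a prime below 2^31 so the result is always a
#' valid R integer seed.
#'
#' @param ... components (coerced to character) identifying the entity.
#' @return integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' hash_seed(42, "ms1", 17)
hash_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                  character(1))
  s <- paste(parts, collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so library code never disturbs the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
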