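# error function via the normal CDF
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# evaluate `code` under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

divisors_360 <- function() {
  d <- 1:360
  d[360 %% d == 0]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
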