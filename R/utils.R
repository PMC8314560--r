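# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' @noRd
r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("outcome is constant (SST = 0); R-squared undefined")
  1 - sum((obs - pred)^2) / sst
}

# Deterministic seed fan-out. Keeps derived seeds in [1, 2^31 - 2] so they are
# valid R integers whatever the master seed.
derive_seed <- function(master, offset) {
  s <- (as.numeric(master) %% 2147483647) + 99991 * as.numeric(offset)
  as.integer(s %% 2147483646) + 1L
}

# Run `expr` under a given seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
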