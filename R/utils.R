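# Internal helpers shared across modules.

.MODULUS <- 2147483647  # 2^31 - 1; all derived seeds stay valid R integers

#' @noRd
.stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Deterministic substream seed from a base seed plus integer/character keys.
# Multiplicative mixing mod 2^31-1 keeps everything in exact double range
# (< 2^53) and platform independent.
#' @noRd
.substream_seed <- function(seed, ...) {
  keys <- list(...)
  h <- (abs(as.numeric(seed)) %% .MODULUS)
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 48271 + abs(as.numeric(k)) + 11) %% .MODULUS
    h <- (h * 16807 + 7) %% .MODULUS
  }
  as.integer(h %% (.MODULUS - 2L) + 1L)
}

# Evaluate expr with a local RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards, so library code never perturbs
# user-level randomness.
#' @noRd
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' @noRd
.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

#' @noRd
.is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

# Connected components of a non-negative adjacency matrix (positive entries
# are edges). Returns an integer membership vector.
#' @noRd
.components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(w[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @noRd
.default_labels <- function(n) {
  if (n == 90L) aal_node_table()$abbreviation else sprintf("R%03d", seq_len(n))
}
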