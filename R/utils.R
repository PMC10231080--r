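# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed for a named substream of a master seed; keeps all
# derived seeds inside the 32-bit signed range R requires.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- (as.numeric(seed) %% 2147483647)
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Shannon entropy of a nonnegative weight vector (zeros dropped).
shannon_entropy <- function(w, base = exp(1)) {
  w <- w[w > 0]
  if (length(w) == 0) return(0)
  p <- w / sum(w)
  -sum(p * log(p, base = base))
}

# sample() without its length-1 surprise.
sample_safe <- function(x, size = length(x), replace = FALSE, prob = NULL) {
  if (length(x) == 1) {
    if (size == 1 && !replace) return(x)
    return(x[sample.int(1, size, replace = replace, prob = prob)])
  }
  sample(x, size, replace = replace, prob = prob)
}
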