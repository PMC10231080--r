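# Independent oracles and fixture builders. Each oracle is a deliberately
# naive implementation (double loops, exhaustive enumeration) kept separate
# from the package's vectorized code paths.

# Brute-force NODF: direct double loop over all row pairs and column pairs.
nodf_oracle <- function(b) {
  b <- b > 0
  score <- function(mat) {
    n <- nrow(mat)
    vals <- c()
    if (n < 2) return(vals)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fi <- sum(mat[i, ]); fj <- sum(mat[j, ])
        if (fi == fj) {
          vals <- c(vals, 0)
        } else {
          hi <- if (fi > fj) i else j
          lo <- if (fi > fj) j else i
          shared <- sum(mat[lo, ] & mat[hi, ])
          vals <- c(vals, 100 * shared / sum(mat[lo, ]))
        }
      }
    }
    vals
  }
  vals <- c(score(b), score(t(b)))
  if (length(vals) == 0) return(0)
  mean(vals)
}

# Random binary matrix with no empty rows/columns.
random_binary_matrix <- function(nr, nc, p = 0.4) {
  repeat {
    b <- matrix(runif(nr * nc) < p, nr, nc)
    if (all(rowSums(b) > 0) && all(colSums(b) > 0)) {
      dimnames(b) <- list(paste0("h", seq_len(nr)), paste0("s", seq_len(nc)))
      return(b * 1L)
    }
  }
}

random_count_matrix <- function(nr, nc, p = 0.5, max_count = 9) {
  b <- random_binary_matrix(nr, nc, p)
  b[b > 0] <- sample.int(max_count, sum(b > 0), replace = TRUE)
  b
}

as_im <- function(m) interaction_matrix(m, quiet = TRUE)

# All set partitions of n items as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (id in seq_len(maxid + 1)) {
      recurse(c(prefix, id), max(maxid, id))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive Barber-Q optimum over every partition of the nodes.
modularity_oracle <- function(m) {
  b <- as.matrix(m) > 0
  L <- sum(b)
  kh <- rowSums(b); ks <- colSums(b)
  Bmat <- b - outer(kh, ks) / L
  R <- nrow(b); S <- ncol(b)
  best <- -Inf
  for (p in all_partitions(R + S)) {
    mh <- p[seq_len(R)]
    ms <- p[R + seq_len(S)]
    q <- 0
    for (mod in unique(p)) {
      q <- q + sum(Bmat[mh == mod, ms == mod, drop = FALSE])
    }
    q <- q / L
    if (q > best) best <- q
  }
  best
}

# Exhaustive mean robustness over all removal orders (naive re-simulation).
rr_oracle <- function(m) {
  mm <- as.matrix(m)
  ids <- rownames(mm)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  curve_area <- function(seq_ids) {
    S0 <- ncol(mm)
    left <- mm
    ys <- 1
    for (id in seq_ids) {
      left[id, ] <- 0
      ys <- c(ys, sum(colSums(left) > 0) / S0)
    }
    xs <- seq(0, 1, length.out = length(ys))
    sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
  }
  mean(vapply(perms(ids), curve_area, numeric(1)))
}

# Two disconnected complete blocks: the planted two-module fixture.
two_block_matrix <- function(nh = 2, ns = 2) {
  m <- matrix(0L, 2 * nh, 2 * ns)
  m[seq_len(nh), seq_len(ns)] <- 1L
  m[nh + seq_len(nh), ns + seq_len(ns)] <- 1L
  dimnames(m) <- list(paste0("h", seq_len(2 * nh)), paste0("s", seq_len(2 * ns)))
  m
}
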