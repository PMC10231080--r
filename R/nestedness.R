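#' NODF nestedness
#'
#' Nestedness by overlap and decreasing fill on the binary incidence. For
#' each pair of rows (and of columns), if their fills differ the pair
#' contributes `100 * overlap / fill_smaller` -- the percentage of the
#' sparser line's links that also occur in the denser line; equal-fill pairs
#' contribute 0. NODF is the mean over all `R(R-1)/2 + S(S-1)/2` pairs, so it
#' lies in `[0, 100]` and is invariant to row/column permutation.
#'
#' @inheritParams node_scores
#' @return NODF in `[0, 100]`.
#' @examples
#' tri <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, byrow = TRUE,
#'   dimnames = list(paste0("h", 1:3), LETTERS[1:3])
#' )
#' nodf(interaction_matrix(tri)) # perfectly nested: 100
#' @export
nodf <- function(m) {
  b <- unclass_matrix(as_interaction(m)) > 0
  mode(b) <- "numeric"
  pair_sum <- function(inc) {
    n <- nrow(inc)
    if (n < 2) return(c(0, 0))
    fill <- rowSums(inc)
    overlap <- tcrossprod(inc)
    lo <- outer(fill, fill, pmin)
    use <- upper.tri(lo) & outer(fill, fill, "!=")
    c(sum(100 * overlap[use] / lo[use]), n * (n - 1) / 2)
  }
  rows <- pair_sum(b)
  cols <- pair_sum(t(b))
  npairs <- rows[2] + cols[2]
  if (npairs == 0) return(0)
  (rows[1] + cols[1]) / npairs
}

#' CE null-model cell probabilities
#'
#' The Bascompte-style CE null: the probability of a link in cell `(h, s)` is
#' the average of the row and column fill proportions of the binary
#' incidence, `p_hs = (k_h/S + k_s/R) / 2`, so generalized hollows and
#' abundant (widely reared) beetles attract links in proportion to their
#' generalization level.
#'
#' @inheritParams node_scores
#' @return A numeric matrix of probabilities in `(0, 1]`, same dimnames.
#' @export
ce_null_probabilities <- function(m) {
  b <- unclass_matrix(as_interaction(m)) > 0
  R <- nrow(b); S <- ncol(b)
  p <- (outer(rowSums(b) / S, rep(1, S)) + outer(rep(1, R), colSums(b) / R)) / 2
  dimnames(p) <- dimnames(b)
  p
}

# One CE draw with the matrix's dimensions; empty rows/columns are redrawn
# (bounded). Returns a binary matrix, or NULL if the retry budget is spent.
draw_ce_matrix <- function(p, max_retry = 100) {
  R <- nrow(p); S <- ncol(p)
  b <- matrix(runif(R * S) < p, R, S)
  for (k in seq_len(max_retry)) {
    er <- rowSums(b) == 0
    ec <- colSums(b) == 0
    if (!any(er) && !any(ec)) return(b)
    if (any(er)) {
      b[er, ] <- matrix(runif(sum(er) * S) < p[er, , drop = FALSE], sum(er), S)
    }
    if (any(ec)) {
      b[, ec] <- matrix(runif(R * sum(ec)) < p[, ec, drop = FALSE], R, sum(ec))
    }
  }
  if (all(rowSums(b) > 0) && all(colSums(b) > 0)) b else NULL
}

new_null_ensemble <- function(observed, null_values, statistic) {
  s <- sd(null_values)
  structure(
    list(
      observed = observed,
      null_values = null_values,
      z = if (isTRUE(s > 0)) (observed - mean(null_values)) / s else NA_real_,
      p_value = (1 + sum(null_values >= observed)) / (1 + length(null_values)),
      statistic = statistic
    ),
    class = "null_ensemble"
  )
}

#' Nestedness significance under the CE null model
#'
#' Draws `replicates` independent Bernoulli incidence matrices from the CE
#' probabilities of the observed web, computes NODF on each, and reports the
#' Monte-Carlo add-one p-value `(1 + #{null >= obs}) / (1 + replicates)`
#' together with the z-score. Degenerate draws (an empty row or column) are
#' redrawn up to a bounded number of retries; the rare draw still degenerate
#' after that is scored on its defined pairs only, with a message.
#'
#' @inheritParams node_scores
#' @param replicates Number of null draws (>= 100 recommended).
#' @param seed Integer seed; fixed seed gives identical null values.
#' @return A `null_ensemble` object; see [tidy()] and [glance()] methods.
#' @export
nestedness_significance <- function(m, replicates = 1000, seed = NULL) {
  m <- as_interaction(m)
  stopifnot(replicates >= 1)
  p <- ce_null_probabilities(m)
  obs <- nodf(m)
  nulls <- with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      b <- draw_ce_matrix(p)
      if (is.null(b)) {
        inform("CE draw still degenerate after retries; scoring defined pairs.")
        b <- matrix(runif(length(p)) < p, nrow(p))
      }
      dimnames(b) <- dimnames(p)
      nodf_binary(b)
    }, numeric(1))
  })
  new_null_ensemble(obs, nulls, "NODF")
}

# NODF on an already-binary matrix (skips container validation; nulls only).
nodf_binary <- function(b) {
  mode(b) <- "integer"
  rownames(b) <- rownames(b) %||% paste0("r", seq_len(nrow(b)))
  colnames(b) <- colnames(b) %||% paste0("c", seq_len(ncol(b)))
  keep_r <- rowSums(b) > 0
  keep_c <- colSums(b) > 0
  b <- b[keep_r, keep_c, drop = FALSE]
  class(b) <- c("interaction_matrix", class(b))
  nodf(b)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> statistic: ", x$statistic,
    "\n  observed = ", format(x$observed, digits = 4),
    ", null mean = ", format(mean(x$null_values), digits = 4),
    " (", length(x$null_values), " replicates)",
    "\n  z = ", format(x$z, digits = 3), ", p = ", format(x$p_value, digits = 3),
    "\n", sep = ""
  )
  invisible(x)
}
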