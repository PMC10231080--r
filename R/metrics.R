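#' Node degrees and species strength
#'
#' Degree is the number of realized links of a node. The dependency of beetle
#' species `s` on hollow `h` is `a_hs / A_.s` (the share of that species'
#' individuals emerging from `h`); a hollow's species strength is the sum of
#' the dependencies of all beetles on it, and symmetrically for beetles
#' (`a_hs / A_h.` summed over hollows). Strengths conserve dependencies:
#' hollow strengths sum to the number of beetle species and beetle strengths
#' to the number of hollows.
#'
#' @param m An [interaction_matrix()] or long data frame coercible to one.
#' @return A tibble with columns `node`, `level` (`"hollow"`/`"beetle"`),
#'   `degree`, `strength`.
#' @examples
#' m <- interaction_matrix(matrix(c(2, 1, 0, 3), 2,
#'   dimnames = list(c("h1", "h2"), c("A", "B"))
#' ))
#' node_scores(m) # hollow strengths 2/3 and 4/3 sum to 2 species
#' @export
node_scores <- function(m) {
  m <- as_interaction(m)
  b <- unclass_matrix(m) > 0
  row_tot <- rowSums(unclass_matrix(m))
  col_tot <- colSums(unclass_matrix(m))
  dep_on_hollow <- sweep(unclass_matrix(m), 2, col_tot, "/") # beetle s depends on h
  dep_on_beetle <- sweep(unclass_matrix(m), 1, row_tot, "/") # hollow h depends on s
  dplyr::bind_rows(
    tibble::tibble(
      node = rownames(m), level = "hollow",
      degree = unname(as.integer(rowSums(b))),
      strength = unname(rowSums(dep_on_hollow))
    ),
    tibble::tibble(
      node = colnames(m), level = "beetle",
      degree = unname(as.integer(colSums(b))),
      strength = unname(colSums(dep_on_beetle))
    )
  )
}

#' Connectance and links per species
#'
#' Connectance is the proportion of realized links among all possible
#' (`L / (R * S)`); links per species is the qualitative ratio `L / (R + S)`,
#' counting both levels as species as is conventional for bipartite webs.
#'
#' @inheritParams node_scores
#' @return A one-row tibble with `links`, `connectance`, `links_per_species`.
#' @export
basic_metrics <- function(m) {
  m <- as_interaction(m)
  L <- sum(m > 0)
  tibble::tibble(
    links = as.integer(L),
    connectance = L / (nrow(m) * ncol(m)),
    links_per_species = L / (nrow(m) + ncol(m))
  )
}

#' Weighted linkage density
#'
#' The quantitative (Bersier-type) mean number of interactions per species:
#' the marginal-weighted average of `2^H` partner diversities, where `H` is
#' the Shannon entropy (base 2) of each row's and column's link weights,
#' halved over the two levels:
#' `LD = 0.5 * (sum_s (A_.s/A) 2^{H_s} + sum_h (A_h./A) 2^{H_h})`.
#'
#' @inheritParams node_scores
#' @return Linkage density, a scalar `>= 1` when all nodes are linked.
#' @export
linkage_density <- function(m) {
  m <- unclass_matrix(as_interaction(m))
  tot <- sum(m)
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  h_rows <- apply(m, 1, shannon_entropy, base = 2)
  h_cols <- apply(m, 2, shannon_entropy, base = 2)
  0.5 * (sum(col_tot / tot * 2^h_cols) + sum(row_tot / tot * 2^h_rows))
}

#' Interaction evenness
#'
#' Shannon evenness of link weights across the whole web: with
#' `p_hs = a_hs / A` over positive cells and `H = -sum p log p` (nats),
#' `IE = H / log(R*S)` for the `"prod"` variant (default; the denominator is
#' the log of all possible links) or `H / log(L)` for `"sum"` (realized
#' links).
#'
#' @inheritParams node_scores
#' @param variant `"prod"` (default) or `"sum"` denominator.
#' @return Evenness in `[0, 1]`.
#' @export
interaction_evenness <- function(m, variant = c("prod", "sum")) {
  variant <- match.arg(variant)
  m <- unclass_matrix(as_interaction(m))
  H <- shannon_entropy(as.numeric(m))
  denom <- switch(variant,
    prod = log(nrow(m) * ncol(m)),
    sum = log(sum(m > 0))
  )
  if (denom == 0) return(0) # single possible/realized link: no evenness defined
  H / denom
}

# Minimum-entropy marginal-preserving integer fill: greedily concentrate mass
# in as few cells as possible.
h2_min_matrix <- function(row_tot, col_tot) {
  m <- matrix(0, length(row_tot), length(col_tot))
  r <- row_tot; co <- col_tot
  while (sum(r) > 0) {
    i <- which.max(r)
    j <- which.max(co)
    a <- min(r[i], co[j])
    m[i, j] <- m[i, j] + a
    r[i] <- r[i] - a
    co[j] <- co[j] - a
  }
  m
}

# Maximum-entropy integer fill: floor of the proportional expectation, then
# remaining units assigned where row and column both still have deficit,
# largest expected cell first.
h2_max_matrix <- function(row_tot, col_tot) {
  n <- sum(row_tot)
  expected <- outer(row_tot, col_tot) / n
  m <- floor(expected)
  r_def <- row_tot - rowSums(m)
  c_def <- col_tot - colSums(m)
  while (sum(r_def) > 0) {
    frac <- expected - m
    cand <- which(outer(r_def > 0, c_def > 0, "&"), arr.ind = TRUE)
    pick <- cand[which.max(frac[cand]), , drop = TRUE]
    m[pick[1], pick[2]] <- m[pick[1], pick[2]] + 1
    r_def[pick[1]] <- r_def[pick[1]] - 1
    c_def[pick[2]] <- c_def[pick[2]] - 1
  }
  m
}

#' Network-level specialization H2'
#'
#' The two-dimensional Shannon entropy of the interaction frequencies,
#' standardized between its marginal-constrained extremes: `H2` is
#' `-sum p_hs log p_hs` over cells; `H2min` is the entropy of a greedy
#' marginal-preserving packing that concentrates interactions in as few cells
#' as possible; `H2max` the entropy of the proportional expected matrix
#' `A_h. * A_.s / A` after integer repair. `H2' = (H2max - H2)/(H2max -
#' H2min)`, clamped to `[0, 1]`; 0 means no discrimination beyond abundance,
#' 1 complete specialization.
#'
#' @inheritParams node_scores
#' @return Specialization in `[0, 1]`.
#' @export
h2prime <- function(m) {
  m <- unclass_matrix(as_interaction(m))
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  h2 <- shannon_entropy(as.numeric(m))
  h2min <- shannon_entropy(as.numeric(h2_min_matrix(row_tot, col_tot)))
  h2max <- shannon_entropy(as.numeric(h2_max_matrix(row_tot, col_tot)))
  if (h2max <= h2min) {
    inform("Degenerate web: H2max equals H2min; returning H2' = 0.")
    return(0)
  }
  min(max((h2max - h2) / (h2max - h2min), 0), 1)
}

#' Variance ratio of the beetle community across hollows
#'
#' Treats hollows as samples: `V = Var(T_h) / sum_s Var(a_hs)` where `T_h`
#' are hollow totals and variances are sample variances (denominator n-1).
#' Values above 1 indicate positive aggregation of species across hollows;
#' values below 1 disaggregation or differential microhabitat association.
#'
#' @inheritParams node_scores
#' @return The variance ratio, a nonnegative scalar.
#' @export
variance_ratio <- function(m) {
  m <- unclass_matrix(as_interaction(m))
  if (nrow(m) < 2) abort("V-ratio needs at least 2 hollows.")
  vt <- var(rowSums(m))
  if (vt == 0) return(0) # identical hollow totals: no aggregation signal
  vt / sum(apply(m, 2, var))
}
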