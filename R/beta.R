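#' Whittaker pairwise beta diversity of two sets
#'
#' With `a` shared and `b`, `c` unique elements,
#' `beta = (a+b+c) / ((2a+b+c)/2) - 1`, i.e. the classical multiplicative
#' Whittaker measure rescaled to `[0, 1]`: 0 for identical sets, 1 for
#' disjoint ones. Two empty sets give 0 by convention.
#'
#' @param set_a,set_b Vectors treated as sets (duplicates ignored).
#' @return Beta in `[0, 1]`.
#' @examples
#' whittaker_beta(c("x", "y"), c("x", "z")) # 0.5
#' @export
whittaker_beta <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  if (a + b + c == 0) return(0)
  (a + b + c) / ((2 * a + b + c) / 2) - 1
}

bray_curtis <- function(x, y) {
  if (sum(x) + sum(y) == 0) return(0)
  sum(abs(x - y)) / (sum(x) + sum(y))
}

link_keys <- function(df) paste(df$hollow, df$species, sep = "\r")

#' Partition between-year network dissimilarity
#'
#' Decomposes whole-network interaction dissimilarity between two networks
#' (typically the same site in two years) into the part driven by rewiring
#' among co-occurring species and the part driven by species turnover:
#' `beta_S` is the Whittaker dissimilarity of species composition, `beta_WN`
#' of the link sets, `beta_OS` of the link sets restricted to nodes present
#' in both networks, and `beta_ST = beta_WN - beta_OS` by construction (it
#' can be negative and is not clamped). Quantitative weighting replaces the
#' set measure on links with Bray-Curtis on link-count vectors over the union
#' of links, under the same restriction logic.
#'
#' @param m1,m2 Two [interaction_matrix()] objects with comparable labels
#'   (hollow labels matched across years under `scope = "both_levels"`).
#' @param scope `"both_levels"` (default; species sets and shared-node
#'   restriction include hollows and beetles, the betalink convention) or
#'   `"beetles_only"` (hollow identity ignored, for designs that sample
#'   different physical hollows each year).
#' @param weighting `"binary"` (default) or `"quantitative"` (Bray-Curtis on
#'   counts) for the link dissimilarities.
#' @return A `beta_partition`: one-row tibble with `beta_S`, `beta_WN`,
#'   `beta_OS`, `beta_ST`, plus `scope` and `weighting`.
#' @export
decompose_beta <- function(m1, m2,
                           scope = c("both_levels", "beetles_only"),
                           weighting = c("binary", "quantitative")) {
  scope <- match.arg(scope)
  weighting <- match.arg(weighting)
  m1 <- as_interaction(m1); m2 <- as_interaction(m2)
  l1 <- as_tibble(m1)[, c("hollow", "species", "count")]
  l2 <- as_tibble(m2)[, c("hollow", "species", "count")]

  nodes1 <- if (scope == "both_levels") {
    c(paste0("h:", rownames(m1)), paste0("b:", colnames(m1)))
  } else {
    colnames(m1)
  }
  nodes2 <- if (scope == "both_levels") {
    c(paste0("h:", rownames(m2)), paste0("b:", colnames(m2)))
  } else {
    colnames(m2)
  }
  beta_s <- whittaker_beta(nodes1, nodes2)

  shared_beetles <- intersect(colnames(m1), colnames(m2))
  shared_hollows <- intersect(rownames(m1), rownames(m2))
  keep_shared <- function(df) {
    ok <- df$species %in% shared_beetles
    if (scope == "both_levels") ok <- ok & df$hollow %in% shared_hollows
    df[ok, , drop = FALSE]
  }
  s1 <- keep_shared(l1); s2 <- keep_shared(l2)

  no_overlap <- nrow(s1) == 0 && nrow(s2) == 0
  link_beta <- function(a, b) {
    if (weighting == "binary") {
      whittaker_beta(link_keys(a), link_keys(b))
    } else {
      keys <- union(link_keys(a), link_keys(b))
      x <- setNames(numeric(length(keys)), keys)
      y <- x
      x[link_keys(a)] <- a$count
      y[link_keys(b)] <- b$count
      bray_curtis(x, y)
    }
  }
  beta_wn <- link_beta(l1, l2)
  if (no_overlap) {
    warn("No shared nodes between the networks; beta_OS set to 0 and beta_ST = beta_WN.")
    beta_os <- 0
  } else {
    beta_os <- link_beta(s1, s2)
  }
  structure(
    tibble::tibble(
      beta_S = beta_s, beta_WN = beta_wn, beta_OS = beta_os,
      beta_ST = beta_wn - beta_os,
      scope = scope, weighting = weighting
    ),
    class = c("beta_partition", "tbl_df", "tbl", "data.frame")
  )
}
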