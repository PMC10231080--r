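#' Specification of a synthetic hollow-beetle network
#'
#' Parameters of the generator that emulates a one-year emergence-trap
#' sample: 16 hollows per woodland (the study design default), a species
#' pool in the 30-120 range, right-skewed (log-normal) species abundances,
#' and a nested link structure produced by a suitability gradient -- cell
#' link probabilities decay as `exp(-shape * (u_i + v_j))` in the normalized
#' hollow and species ranks and are rescaled to the target connectance.
#'
#' @param n_hollows Number of tree hollows (default 16).
#' @param n_species Number of beetle species (default 60).
#' @param nestedness_shape Nonnegative gradient steepness; 0 is random fill,
#'   larger values give steeper, more nested webs (default 4).
#' @param target_connectance Expected fraction of realized links (default
#'   0.15, the connectance range of hollow-saproxylic webs).
#' @param abundance_log_mean,abundance_log_sd Log-normal parameters of the
#'   per-species expected counts (defaults 1 and 1).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_hollows = 16, n_species = 60,
                           nestedness_shape = 4, target_connectance = 0.15,
                           abundance_log_mean = 1, abundance_log_sd = 1,
                           seed = NULL) {
  stopifnot(
    n_hollows >= 2, n_species >= 2,
    target_connectance > 0, target_connectance <= 1,
    nestedness_shape >= 0, abundance_log_sd >= 0
  )
  structure(
    list(
      n_hollows = n_hollows, n_species = n_species,
      nestedness_shape = nestedness_shape,
      target_connectance = target_connectance,
      abundance_log_mean = abundance_log_mean,
      abundance_log_sd = abundance_log_sd,
      seed = seed
    ),
    class = "synthetic_spec"
  )
}

#' Specification of interannual change for a synthetic pair
#'
#' Ground-truth dials for the temporal beta decomposition: `turnover` is the
#' fraction of beetle species replaced in year 2, `rewiring` the expected
#' fraction of each retained species' links moved to other hollows (degree
#' preserved, so rewiring changes beta_OS without touching beta_S or
#' connectance), and `abundance_drift` a multiplicative count scaling.
#'
#' @param turnover Fraction of beetle species replaced at t2, in `[0, 1]`.
#' @param rewiring Expected fraction of links moved per retained species,
#'   in `[0, 1]`.
#' @param abundance_drift Multiplicative count scaling (> 0; links never
#'   drop below one individual).
#' @param seed Integer seed.
#' @return A `temporal_spec` list.
#' @export
temporal_spec <- function(turnover = 0.3, rewiring = 0.2,
                          abundance_drift = 1, seed = NULL) {
  stopifnot(
    turnover >= 0, turnover <= 1, rewiring >= 0, rewiring <= 1,
    abundance_drift > 0
  )
  structure(
    list(turnover = turnover, rewiring = rewiring,
         abundance_drift = abundance_drift, seed = seed),
    class = "temporal_spec"
  )
}

# Link probability table of a spec: exp(-shape*(u_i+v_j)) rescaled so the
# mean equals the target connectance, clamped at 1.
link_probabilities <- function(spec) {
  u <- if (spec$n_hollows > 1) (seq_len(spec$n_hollows) - 1) / (spec$n_hollows - 1) else 0
  v <- if (spec$n_species > 1) (seq_len(spec$n_species) - 1) / (spec$n_species - 1) else 0
  w <- exp(-spec$nestedness_shape * outer(u, v, "+"))
  p <- w * spec$target_connectance / mean(w)
  # clamping changes the mean; rescale the rest a few times to compensate
  for (i in 1:20) {
    over <- p > 1
    if (!any(over)) break
    p[over] <- 1
    deficit <- spec$target_connectance * length(p) - sum(p)
    if (deficit <= 0) break
    free <- !over
    p[free] <- p[free] * (1 + deficit / sum(p[free]))
  }
  pmin(p, 1)
}

draw_counts <- function(b, lambda) {
  counts <- matrix(0L, nrow(b), ncol(b))
  idx <- which(b, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    counts[idx] <- 1L + rpois(nrow(idx), lambda[idx[, 2]])
  }
  counts
}

#' Generate a synthetic interaction network
#'
#' Draws the binary incidence cell-wise from the spec's nested link
#' probabilities, resampling empty rows/columns up to `max_retry` times (a
#' line still empty after that receives one probability-weighted link, with
#' a message, so steep suitability gradients remain generable), then assigns
#' each link a count of `1 + Poisson(lambda_s)` where `lambda_s` is the
#' species' log-normal expected abundance -- links are never zero and
#' species abundance distributions come out right-skewed.
#'
#' @param spec A [synthetic_spec()].
#' @param site,year Labels attached to the result.
#' @param max_retry Retry budget for degenerate rows/columns (default 100).
#' @return An [interaction_matrix()] of dimensions
#'   `n_hollows x n_species`.
#' @export
generate_network <- function(spec, site = NULL, year = NULL, max_retry = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- link_probabilities(spec)
  with_seed(spec$seed, {
    b <- matrix(runif(length(p)) < p, nrow(p))
    for (k in seq_len(max_retry)) {
      er <- rowSums(b) == 0
      ec <- colSums(b) == 0
      if (!any(er) && !any(ec)) break
      if (any(er)) {
        b[er, ] <- matrix(runif(sum(er) * ncol(b)) < p[er, , drop = FALSE],
                          sum(er), ncol(b))
      }
      if (any(ec)) {
        b[, ec] <- matrix(runif(nrow(b) * sum(ec)) < p[, ec, drop = FALSE],
                          nrow(b), sum(ec))
      }
    }
    er <- which(rowSums(b) == 0)
    ec <- which(colSums(b) == 0)
    if (length(er) > 0 || length(ec) > 0) {
      # steep gradients make the sparsest lines near-impossible to fill by
      # rejection; give each a single probability-weighted link instead
      inform(paste0(
        "Placing a minimal link in ", length(er) + length(ec),
        " line(s) still empty after ", max_retry, " retries."
      ))
      for (i in er) b[i, sample_safe(seq_len(ncol(b)), 1, prob = pmax(p[i, ], 1e-12))] <- TRUE
      for (j in which(colSums(b) == 0)) {
        b[sample_safe(seq_len(nrow(b)), 1, prob = pmax(p[, j], 1e-12)), j] <- TRUE
      }
    }
    lambda <- rlnorm(spec$n_species, spec$abundance_log_mean, spec$abundance_log_sd)
    counts <- draw_counts(b, lambda)
    dimnames(counts) <- list(
      sprintf("h%02d", seq_len(spec$n_hollows)),
      sprintf("sp%03d", seq_len(spec$n_species))
    )
    interaction_matrix(counts, site = site, year = year, quiet = TRUE)
  })
}

#' Generate a paired-year network with known turnover and rewiring
#'
#' Year 1 is `base`; year 2 replaces `ceiling(turnover * S)` uniformly
#' chosen beetle species with fresh species (link profiles drawn anew with
#' the replaced species' degrees, placed by hollow fill; counts drawn from
#' the base count distribution), then moves a `Binomial(k_s, rewiring)`
#' number of each retained species' links to uniformly chosen currently
#' unlinked hollows (degree preserved), and finally scales counts by
#' `abundance_drift` (rounded, links floored at 1). Hollow labels persist
#' across years; `relabel_hollows = TRUE` instead relabels year-2 hollows to
#' emulate a design that samples different physical hollows each period.
#'
#' @param base An [interaction_matrix()] (year 1).
#' @param tspec A [temporal_spec()].
#' @param relabel_hollows Give year-2 hollows fresh labels (default `FALSE`).
#' @return A list with elements `t1` and `t2`.
#' @export
generate_temporal_pair <- function(base, tspec, relabel_hollows = FALSE) {
  stopifnot(inherits(tspec, "temporal_spec"))
  base <- as_interaction(base)
  mm <- unclass_matrix(base)
  R <- nrow(mm); S <- ncol(mm)
  out <- with_seed(tspec$seed, {
    m2 <- mm
    n_replace <- ceiling(tspec$turnover * S)
    replaced <- if (n_replace > 0) sort(sample_safe(seq_len(S), n_replace)) else integer(0)
    retained <- setdiff(seq_len(S), replaced)

    # rewiring of retained species: move links, degree preserved
    for (j in retained) {
      linked <- which(m2[, j] > 0)
      unlinked <- which(m2[, j] == 0)
      if (length(linked) == 0 || length(unlinked) == 0) next
      n_move <- rbinom(1, length(linked), tspec$rewiring)
      n_move <- min(n_move, length(unlinked))
      if (n_move == 0) next
      from <- sample_safe(linked, n_move)
      to <- sample_safe(unlinked, n_move)
      m2[cbind(to, j)] <- m2[cbind(from, j)]
      m2[cbind(from, j)] <- 0L
    }

    # species turnover: fresh profiles with the replaced species' degrees
    hollow_fill <- rowSums(mm > 0)
    mean_count <- mean(mm[mm > 0])
    for (j in replaced) {
      k <- sum(mm[, j] > 0)
      hosts <- sample_safe(seq_len(R), min(k, R), prob = hollow_fill)
      new_col <- integer(R)
      new_col[hosts] <- 1L + rpois(length(hosts), max(mean_count - 1, 0.5))
      m2[, j] <- new_col
    }

    if (tspec$abundance_drift != 1) {
      pos <- m2 > 0
      m2[pos] <- pmax(1L, as.integer(round(m2[pos] * tspec$abundance_drift)))
    }

    colnames(m2)[replaced] <- sprintf("new%03d", seq_along(replaced))
    if (relabel_hollows) rownames(m2) <- paste0(rownames(m2), "_t2")
    m2
  })
  t2 <- interaction_matrix(out, site = attr(base, "site"), year = "t2", quiet = TRUE)
  t1 <- base
  attr(t1, "year") <- attr(base, "year") %||% "t1"
  list(t1 = t1, t2 = t2)
}

#' Generate a full multi-site, two-year study bundle
#'
#' Emulates the three-woodland, paired-year design: one synthetic network
#' per site, its temporal pair, and the pooled park-scale pair (hollow sets
#' concatenated, species unioned). Deterministic under `seed`.
#'
#' @param specs Named list of three (or more) [synthetic_spec()]s, one per
#'   site; names are the site labels.
#' @param tspecs List of [temporal_spec()]s, same names.
#' @param seed Integer master seed; per-site seeds are derived from it, so
#'   any per-spec seeds are overridden.
#' @return A tibble with columns `site`, `year`, `network` (list column of
#'   [interaction_matrix()]), including the pooled `"park"` rows.
#' @export
generate_study_bundle <- function(specs = default_site_specs(),
                                  tspecs = default_site_tspecs(),
                                  seed = 1) {
  stopifnot(length(specs) >= 1, setequal(names(specs), names(tspecs)))
  rows <- purrr::map_dfr(names(specs), function(site) {
    sp <- specs[[site]]
    ts <- tspecs[[site]]
    sp$seed <- substream_seed(seed, paste0("net_", site))
    ts$seed <- substream_seed(seed, paste0("time_", site))
    base <- generate_network(sp, site = site, year = "t1")
    pair <- generate_temporal_pair(base, ts)
    tibble::tibble(
      site = site, year = c("t1", "t2"), network = list(pair$t1, pair$t2)
    )
  })
  park <- purrr::map_dfr(c("t1", "t2"), function(yr) {
    nets <- rows$network[rows$year == yr]
    tibble::tibble(
      site = "park", year = yr,
      network = list(pool_networks(nets, site = "park"))
    )
  })
  dplyr::bind_rows(park, rows)
}

#' Default site specifications of the synthetic study
#'
#' Three woodland types with 16 hollows each and species pools and
#' connectances in the range of the site-level webs (roughly 45-75 species,
#' connectance 0.12-0.20), plus moderate nestedness gradients.
#'
#' @return A named list of [synthetic_spec()]s.
#' @export
default_site_specs <- function() {
  list(
    deciduous = synthetic_spec(
      n_hollows = 16, n_species = 75, nestedness_shape = 4,
      target_connectance = 0.18
    ),
    riparian = synthetic_spec(
      n_hollows = 16, n_species = 60, nestedness_shape = 4,
      target_connectance = 0.16
    ),
    sclerophyllous = synthetic_spec(
      n_hollows = 16, n_species = 50, nestedness_shape = 4,
      target_connectance = 0.14
    )
  )
}

#' Default interannual-change specifications
#'
#' Species turnover around 0.5 with moderate rewiring and a mild abundance
#' decline, the regime the beta decomposition is designed to separate.
#'
#' @return A named list of [temporal_spec()]s.
#' @export
default_site_tspecs <- function() {
  list(
    deciduous = temporal_spec(turnover = 0.5, rewiring = 0.25, abundance_drift = 0.8),
    riparian = temporal_spec(turnover = 0.5, rewiring = 0.3, abundance_drift = 0.7),
    sclerophyllous = temporal_spec(turnover = 0.5, rewiring = 0.3, abundance_drift = 0.8)
  )
}
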