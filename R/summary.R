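#' Full metric bundle for one network
#'
#' Computes the report-table metric set for a single network: species and
#' individual counts, NODF with its CE-null p-value and z-score,
#' connectance, links per species, weighted linkage density, interaction
#' evenness, H2' specialization, the V-ratio, and the three robustness
#' values RR/RM/RL.
#'
#' @inheritParams node_scores
#' @param null_replicates CE null draws behind the NODF p-value.
#' @param robustness_reps Random removal orders behind RR.
#' @param seed Integer master seed (substreams derived for the null model
#'   and the random removals).
#' @param variant Third-scenario reading for RL; see [extinction_sequence()].
#' @param ie_variant Denominator variant for [interaction_evenness()].
#' @return A one-row tibble; `site` and `year` are carried over from the
#'   matrix attributes.
#' @export
network_summary <- function(m, null_replicates = 100, robustness_reps = 100,
                            seed = NULL, variant = c("degree", "abundance"),
                            ie_variant = c("prod", "sum")) {
  variant <- match.arg(variant)
  ie_variant <- match.arg(ie_variant)
  m <- as_interaction(m)
  basics <- basic_metrics(m)
  nest <- nestedness_significance(
    m, replicates = null_replicates,
    seed = if (is.null(seed)) NULL else substream_seed(seed, "nodf")
  )
  rob <- robustness_suite(
    m, random_reps = robustness_reps,
    seed = if (is.null(seed)) NULL else substream_seed(seed, "rob"),
    variant = variant
  )
  tibble::tibble(
    site = attr(m, "site") %||% NA_character_,
    year = attr(m, "year") %||% NA_character_,
    n_hollows = nrow(m),
    n_species = ncol(m),
    n_individuals = sum(m),
    nodf = nest$observed,
    nodf_z = nest$z,
    nodf_p = nest$p_value,
    connectance = basics$connectance,
    links_per_species = basics$links_per_species,
    linkage_density = linkage_density(m),
    interaction_evenness = interaction_evenness(m, ie_variant),
    h2prime = h2prime(m),
    v_ratio = if (nrow(m) >= 2) variance_ratio(m) else NA_real_,
    RR = rob$summary$RR,
    RM = rob$summary$RM,
    RL = rob$summary$RL
  )
}

#' Analysis configuration
#'
#' Bundles every tunable of [run_pipeline()] with the package defaults:
#' 100 CE null draws, 100 random removal orders, the species-strength core
#' benchmark of 4, the degree reading of the third removal scenario, the
#' both-levels beta scope, and 200 bootstrap replicates for diversity.
#'
#' @param null_replicates CE null draws per network (>= 1).
#' @param random_seed Master seed; every stochastic step draws a named
#'   substream from it.
#' @param robustness_random_reps Random removal orders behind RR.
#' @param strength_core_threshold Quantitative core benchmark (> 0).
#' @param removal_order_variant `"degree"` or `"abundance"`.
#' @param beta_node_scope `"both_levels"` or `"beetles_only"`.
#' @param beta_weighting `"binary"` or `"quantitative"`.
#' @param bootstrap_reps Bootstrap replicates for diversity CIs.
#' @param ie_variant Interaction-evenness denominator.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(null_replicates = 100,
                            random_seed = 1,
                            robustness_random_reps = 100,
                            strength_core_threshold = 4,
                            removal_order_variant = c("degree", "abundance"),
                            beta_node_scope = c("both_levels", "beetles_only"),
                            beta_weighting = c("binary", "quantitative"),
                            bootstrap_reps = 200,
                            ie_variant = c("prod", "sum")) {
  stopifnot(
    null_replicates >= 1, robustness_random_reps >= 1,
    strength_core_threshold > 0, bootstrap_reps >= 1
  )
  structure(
    list(
      null_replicates = null_replicates,
      random_seed = random_seed,
      robustness_random_reps = robustness_random_reps,
      strength_core_threshold = strength_core_threshold,
      removal_order_variant = match.arg(removal_order_variant),
      beta_node_scope = match.arg(beta_node_scope),
      beta_weighting = match.arg(beta_weighting),
      bootstrap_reps = bootstrap_reps,
      ie_variant = match.arg(ie_variant)
    ),
    class = "analysis_config"
  )
}

#' Run the complete analysis pipeline
#'
#' For every analysis scale (each site plus the pooled park) and year:
#' the full metric bundle (with NODF significance and robustness), the
#' Hill-diversity estimates with bootstrap CIs and coverage, the hollow
#' core profile, the between-year beta partition, and the two
#' core-degradation threat scenarios with their own metric bundles. All
#' randomness flows from `config$random_seed` through named substreams, so
#' a rerun with the same inputs is identical.
#'
#' @param networks A tibble with columns `site`, `year`, `network` (list of
#'   [interaction_matrix()]), exactly two years per site -- e.g. the output
#'   of [generate_study_bundle()]. If no `"park"` rows are present they are
#'   added by pooling the sites per year.
#' @param config An [analysis_config()].
#' @param include_modularity Also run [modularity_significance()] per
#'   network (slower; default `FALSE`).
#' @return A `hollownet_report` list of tibbles: `summaries` (per
#'   site/year/scenario), `beta`, `diversity`, `cores`, and
#'   `scenario_replacements`.
#' @export
run_pipeline <- function(networks, config = analysis_config(),
                         include_modularity = FALSE) {
  stopifnot(is.data.frame(networks),
            all(c("site", "year", "network") %in% names(networks)))
  bad <- networks |>
    dplyr::count(.data$site) |>
    dplyr::filter(.data$n != 2)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Each site needs exactly two year entries; offending: ",
      paste(bad$site, collapse = ", ")
    ))
  }
  years <- sort(unique(networks$year))
  if (length(years) != 2) abort("Exactly two distinct year labels are required.")
  if (!"park" %in% networks$site) {
    park <- purrr::map_dfr(years, function(yr) {
      nets <- networks$network[networks$year == yr & networks$site != "park"]
      tibble::tibble(site = "park", year = yr,
                     network = list(pool_networks(nets, site = "park")))
    })
    networks <- dplyr::bind_rows(park, networks)
  }
  seed_for <- function(...) substream_seed(config$random_seed, paste(..., sep = "_"))

  per_net <- purrr::pmap(networks, function(site, year, network) {
    m <- network
    summ <- network_summary(
      m, null_replicates = config$null_replicates,
      robustness_reps = config$robustness_random_reps,
      seed = seed_for("summary", site, year),
      variant = config$removal_order_variant,
      ie_variant = config$ie_variant
    )
    if (include_modularity) {
      mod <- modularity_significance(
        m, replicates = config$null_replicates,
        seed = seed_for("mod", site, year)
      )
      summ$modularity <- mod$observed
      summ$modularity_p <- mod$p_value
    }
    div <- purrr::map_dfr(c(0, 1), function(q) {
      diversity_with_ci(
        colSums(unclass_matrix(m)), q = q, B = config$bootstrap_reps,
        seed = seed_for("div", site, year, q)
      )
    })
    div$site <- site; div$year <- year
    cores <- core_profile(m, strength_threshold = config$strength_core_threshold)
    cores$site <- site; cores$year <- year
    list(summary = summ, diversity = div, cores = cores)
  })

  summaries <- purrr::map_dfr(per_net, "summary")
  summaries$scenario <- NA_character_

  beta <- networks |>
    dplyr::distinct(.data$site) |>
    dplyr::pull("site") |>
    purrr::map_dfr(function(st) {
      pair <- networks[networks$site == st, ]
      pair <- pair[order(pair$year), ]
      bp <- decompose_beta(
        pair$network[[1]], pair$network[[2]],
        scope = config$beta_node_scope, weighting = config$beta_weighting
      )
      dplyr::mutate(tibble::as_tibble(bp), site = st, .before = 1)
    })

  scen <- purrr::pmap(networks[networks$year == years[2], ],
                      function(site, year, network) {
    ss <- scenario_suite(
      network, strength_threshold = config$strength_core_threshold,
      null_replicates = config$null_replicates,
      robustness_reps = config$robustness_random_reps,
      seed = seed_for("scen", site),
      variant = config$removal_order_variant
    )
    summ <- ss$summaries
    summ$site <- site
    summ$year <- year
    repl <- dplyr::bind_rows(
      dplyr::mutate(attr(ss$A, "replacements"), scenario = "A_qualitative"),
      dplyr::mutate(attr(ss$B, "replacements"), scenario = "B_quantitative")
    )
    if (nrow(repl) > 0) repl$site <- site
    list(summary = summ, replacements = repl)
  })

  structure(
    list(
      summaries = dplyr::bind_rows(summaries, purrr::map_dfr(scen, "summary")),
      beta = beta,
      diversity = purrr::map_dfr(per_net, "diversity"),
      cores = purrr::map_dfr(per_net, "cores"),
      scenario_replacements = purrr::map_dfr(scen, "replacements"),
      config = config
    ),
    class = "hollownet_report"
  )
}

#' @export
print.hollownet_report <- function(x, ...) {
  cat("<hollownet_report>\n")
  cat("  summaries: ", nrow(x$summaries), " network/scenario rows\n", sep = "")
  cat("  beta:      ", nrow(x$beta), " site pairs\n", sep = "")
  cat("  diversity: ", nrow(x$diversity), " estimates\n", sep = "")
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits `summaries.csv` (metric-by-network layout via
#' [write_summary_table()]), `beta.csv`, `diversity.csv` and `cores.csv`
#' under `dir`.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hollownet_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_table(report$summaries, file.path(dir, "summaries.csv"))
  readr::write_csv(report$beta, file.path(dir, "beta.csv"))
  readr::write_csv(report$diversity, file.path(dir, "diversity.csv"))
  readr::write_csv(report$cores, file.path(dir, "cores.csv"))
  invisible(dir)
}
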