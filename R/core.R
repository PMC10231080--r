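#' Core-periphery profile of the tree hollows
#'
#' Qualitative cores follow the generalist-core statistic
#' `Gc = (k_i - k_mean) / sigma_k`, the hollow's degree standardized by the
#' mean and (population) standard deviation of hollow degrees; hollows with
#' `Gc > 1` form the generalist core. Quantitative cores use species
#' strength, with nested tiers above 4 and above 5 (the two benchmarks used
#' for strongly interacting hollows).
#'
#' @inheritParams node_scores
#' @param strength_threshold Lower benchmark for the quantitative core
#'   (default 4; the `> threshold + 1` tier is reported alongside).
#' @param sd_type `"population"` (default) or `"sample"` standard deviation
#'   in the Gc standardization.
#' @return A `core_profile` tibble, one row per hollow: `hollow`, `degree`,
#'   `gc`, `strength`, `qualitative_core`, `strength_tier`
#'   (`"none"`, `"gt4"`, `"gt5"` for the default threshold).
#' @examples
#' m <- interaction_matrix(
#'   rbind(
#'     h1 = c(1, 1, 1, 1, 1), h2 = c(1, 0, 0, 0, 0),
#'     h3 = c(0, 1, 0, 0, 0), h4 = c(0, 0, 1, 0, 0)
#'   ) |> `colnames<-`(LETTERS[1:5])
#' )
#' core_profile(m) # degrees 5,1,1,1: only h1 is a qualitative core
#' @export
core_profile <- function(m, strength_threshold = 4,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(strength_threshold > 0)
  m <- as_interaction(m)
  scores <- node_scores(m)
  hollows <- scores[scores$level == "hollow", ]
  k <- hollows$degree
  sigma <- if (sd_type == "population") {
    sqrt(mean((k - mean(k))^2))
  } else {
    sd(k)
  }
  if (is.na(sigma) || sigma == 0) {
    warn("All hollow degrees equal: sigma_k = 0, no qualitative core.")
    gc <- rep(0, length(k))
  } else {
    gc <- (k - mean(k)) / sigma
  }
  hi <- strength_threshold + 1
  structure(
    tibble::tibble(
      hollow = hollows$node,
      degree = k,
      gc = gc,
      strength = hollows$strength,
      qualitative_core = gc > 1,
      strength_tier = dplyr::case_when(
        hollows$strength > hi ~ paste0("gt", hi),
        hollows$strength > strength_threshold ~ paste0("gt", strength_threshold),
        TRUE ~ "none"
      )
    ),
    class = c("core_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Degrade core hollows into the least suitable ones
#'
#' The threat-scenario transform: each core hollow (taken in descending
#' degree order) has its whole count row replaced by a copy of a donor row
#' from the worst non-core hollows (ascending degree, cycled if cores
#' outnumber donors), emulating the loss of microhabitat suitability of the
#' best hollows. Species left with no individuals are dropped (logged), so
#' species and individual totals can only shrink or stay equal.
#'
#' @inheritParams node_scores
#' @param core Character vector of core hollow ids (possibly empty).
#' @return A `scenario_matrix`: the transformed [interaction_matrix()] with a
#'   `replacements` attribute (tibble `core`, `donor`) and a
#'   `dropped_species` attribute.
#' @export
transform_cores <- function(m, core) {
  m <- as_interaction(m)
  stopifnot(all(core %in% rownames(m)))
  if (length(core) == 0) {
    warn("Empty core: transform is the identity.")
    out <- m
    attr(out, "replacements") <- tibble::tibble(core = character(), donor = character())
    attr(out, "dropped_species") <- character()
    class(out) <- unique(c("scenario_matrix", class(out)))
    return(out)
  }
  mm <- unclass_matrix(m)
  deg <- rowSums(mm > 0)
  abun <- rowSums(mm)
  donors <- setdiff(rownames(mm), core)
  if (length(donors) == 0) abort("No non-core hollow available as donor.")
  core_sorted <- core[order(-deg[core], -abun[core], core)]
  donors_sorted <- donors[order(deg[donors], abun[donors], donors)]
  donor_for <- donors_sorted[((seq_along(core_sorted) - 1) %% length(donors_sorted)) + 1]
  out <- mm
  for (i in seq_along(core_sorted)) {
    out[core_sorted[i], ] <- mm[donor_for[i], ]
  }
  dropped <- colnames(out)[colSums(out) == 0]
  if (length(dropped) > 0) {
    inform(paste0(
      "Species lost in core transform: ", paste(dropped, collapse = ", ")
    ))
  }
  res <- interaction_matrix(out, site = attr(m, "site"), year = attr(m, "year"),
                            quiet = TRUE)
  attr(res, "replacements") <- tibble::tibble(core = core_sorted, donor = donor_for)
  attr(res, "dropped_species") <- dropped
  class(res) <- unique(c("scenario_matrix", class(res)))
  res
}

#' Run both core-degradation threat scenarios
#'
#' Scenario A degrades the qualitative (Gc) core, scenario B the
#' quantitative (species strength above the benchmark) core; each
#' transformed web is then passed through the complete metric, nestedness
#' significance and robustness pipeline so the scenarios can be compared
#' with the original network column by column.
#'
#' @inheritParams node_scores
#' @param strength_threshold Benchmark for the quantitative core (default 4).
#' @param null_replicates CE null draws for the nestedness test.
#' @param robustness_reps Random orders for RR.
#' @param seed Integer master seed.
#' @param variant Passed to [robustness_suite()].
#' @return A list with `A` and `B` (`scenario_matrix` objects) and
#'   `summaries`, a tibble with one [network_summary()] row per scenario.
#' @export
scenario_suite <- function(m, strength_threshold = 4, null_replicates = 100,
                           robustness_reps = 100, seed = NULL,
                           variant = c("degree", "abundance")) {
  variant <- match.arg(variant)
  m <- as_interaction(m)
  prof <- core_profile(m, strength_threshold = strength_threshold)
  core_a <- prof$hollow[prof$qualitative_core]
  core_b <- prof$hollow[prof$strength > strength_threshold]
  seed_for <- function(name) if (is.null(seed)) NULL else substream_seed(seed, name)
  mk <- function(core, label, sname) {
    tm <- suppressWarnings(transform_cores(m, core))
    summ <- network_summary(
      tm, null_replicates = null_replicates,
      robustness_reps = robustness_reps, seed = seed_for(sname),
      variant = variant
    )
    summ$scenario <- label
    list(matrix = tm, summary = summ)
  }
  a <- mk(core_a, "A_qualitative", "scenA")
  b <- mk(core_b, "B_quantitative", "scenB")
  list(
    A = a$matrix, B = b$matrix,
    summaries = dplyr::bind_rows(a$summary, b$summary)
  )
}
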