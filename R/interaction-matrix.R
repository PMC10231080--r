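#' Interaction matrices for hollow-beetle networks
#'
#' An `interaction_matrix` is a labelled matrix of nonnegative integer
#' emergence counts with tree hollows as rows (the lower, removable level)
#' and saproxylic beetle species as columns (the higher level), carrying
#' `site` and `year` labels as attributes. It is the universal input of every
#' analysis in hollownet.
#'
#' Validation enforces the container's invariants: integer counts `>= 0`,
#' unique labels on both axes, and no all-zero row or column. Hollows with no
#' emerging saproxylics (and species never reared) carry no interactions, so
#' zero lines are dropped with a warning listing them -- never kept silently.
#'
#' @param x A long data frame with columns `hollow`, `species`, `count`, or a
#'   numeric matrix with hollow row names and species column names.
#' @param site Optional site label (e.g., a woodland type or `"park"`).
#' @param year Optional year/period label (e.g., `"t1"`, `"t2"`).
#' @param quiet If `TRUE`, suppress the zero-line warning.
#'
#' @return An `interaction_matrix`: an integer matrix with `site` and `year`
#'   attributes.
#' @examples
#' df <- tibble::tribble(
#'   ~hollow, ~species, ~count,
#'   "h1", "A", 2L,
#'   "h2", "A", 1L,
#'   "h2", "B", 3L
#' )
#' m <- interaction_matrix(df, site = "riparian", year = "t1")
#' dim(m)
#' @export
interaction_matrix <- function(x, site = NULL, year = NULL, quiet = FALSE) {
  if (is.data.frame(x)) {
    x <- long_to_matrix(x)
  }
  if (!is.matrix(x)) {
    abort("`x` must be a data frame (hollow, species, count) or a matrix.")
  }
  m <- validate_counts(x)
  m <- drop_zero_lines(m, quiet = quiet)
  attr(m, "site") <- site
  attr(m, "year") <- year
  class(m) <- c("interaction_matrix", class(m))
  m
}

long_to_matrix <- function(df) {
  names(df) <- tolower(names(df))
  needed <- c("hollow", "species", "count")
  if (!all(needed %in% names(df))) {
    abort("Long-form input needs columns `hollow`, `species`, `count`.")
  }
  dup <- df |>
    dplyr::count(.data$hollow, .data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (hollow, species) records: ",
      paste(dup$hollow, dup$species, sep = ":", collapse = ", ")
    ))
  }
  wide <- df |>
    dplyr::select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(
      names_from = "species", values_from = "count", values_fill = 0
    )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$hollow)
  m
}

validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("Matrix input needs hollow row names and species column names.")
  }
  if (anyDuplicated(rownames(m))) {
    abort(paste0(
      "Duplicate hollow labels: ",
      paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0(
      "Duplicate species labels: ",
      paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")
    ))
  }
  if (any(is.na(m)) || !is.numeric(m)) {
    bad <- which(is.na(m) | !is.finite(m), arr.ind = TRUE)[1, , drop = TRUE]
    abort(paste0(
      "Non-numeric count at hollow '", rownames(m)[bad[1]],
      "', species '", colnames(m)[bad[2]], "'."
    ))
  }
  if (any(m < 0) || any(m != round(m))) {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)[1, , drop = TRUE]
    abort(paste0(
      "Counts must be nonnegative integers; offending cell: hollow '",
      rownames(m)[bad[1]], "', species '", colnames(m)[bad[2]],
      "' = ", m[bad[1], bad[2]], "."
    ))
  }
  storage.mode(m) <- "integer"
  m
}

drop_zero_lines <- function(m, quiet = FALSE) {
  repeat {
    zr <- rownames(m)[rowSums(m) == 0]
    zc <- colnames(m)[colSums(m) == 0]
    if (length(zr) == 0 && length(zc) == 0) break
    if (!quiet) {
      warn(paste0(
        "Dropping all-zero lines: ",
        if (length(zr)) paste0("hollows [", paste(zr, collapse = ", "), "] "),
        if (length(zc)) paste0("species [", paste(zc, collapse = ", "), "]")
      ))
    }
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  }
  if (nrow(m) == 0 || ncol(m) == 0) {
    abort("Matrix has no positive interactions after validation.")
  }
  m
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(
    "<interaction_matrix> ", nrow(x), " hollows x ", ncol(x), " species, ",
    sum(x), " individuals", sep = ""
  )
  site <- attr(x, "site"); year <- attr(x, "year")
  if (!is.null(site) || !is.null(year)) {
    cat(" [", paste(c(site, year), collapse = ", "), "]", sep = "")
  }
  cat("\n")
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(m) {
  matrix(as.vector(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' @export
as.matrix.interaction_matrix <- function(x, ...) unclass_matrix(x)

#' Long-form view of an interaction matrix
#'
#' Returns the positive cells as a tidy edge list, one row per realized
#' hollow-species link.
#'
#' @param x An [interaction_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `hollow`, `species`, `count`, `site`, `year`.
#' @export
as_tibble.interaction_matrix <- function(x, ...) {
  idx <- which(x > 0, arr.ind = TRUE)
  tibble::tibble(
    hollow = rownames(x)[idx[, 1]],
    species = colnames(x)[idx[, 2]],
    count = as.integer(x[idx]),
    site = attr(x, "site") %||% NA_character_,
    year = attr(x, "year") %||% NA_character_
  ) |>
    dplyr::arrange(.data$hollow, .data$species)
}

as_interaction <- function(m) {
  if (inherits(m, "interaction_matrix")) return(m)
  interaction_matrix(m, quiet = TRUE)
}

#' Pool several networks into one larger network
#'
#' Builds the park-scale network from site-level networks of the same year:
#' hollow sets are concatenated (hollow labels prefixed with their site so
#' they stay unique) and species columns are unioned, with counts of shared
#' species kept per hollow.
#'
#' @param networks A list of [interaction_matrix()] objects from one year.
#' @param site Label for the pooled network (default `"park"`).
#' @param prefix_hollows Prefix hollow ids with their site label to keep them
#'   unique across sites (default `TRUE`; set `FALSE` if already unique).
#' @return An [interaction_matrix()] covering all hollows and species.
#' @export
pool_networks <- function(networks, site = "park", prefix_hollows = TRUE) {
  stopifnot(length(networks) >= 1)
  years <- unique(purrr::map_chr(networks, ~ attr(.x, "year") %||% NA_character_))
  long <- purrr::map_dfr(networks, function(m) {
    df <- as_tibble.interaction_matrix(as_interaction(m))
    if (prefix_hollows && !is.na(df$site[1])) {
      df$hollow <- paste(df$site, df$hollow, sep = ".")
    }
    df
  })
  interaction_matrix(
    long[, c("hollow", "species", "count")],
    site = site,
    year = if (length(years) == 1) years else NULL,
    quiet = TRUE
  )
}
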