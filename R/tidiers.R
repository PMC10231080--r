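# broom-style tidiers for hollownet result objects.

#' Tidy a null-model ensemble
#'
#' @param x A `null_ensemble` from [nestedness_significance()] or
#'   [modularity_significance()].
#' @param ... Unused.
#' @return One row per null draw (`replicate`, `value`) plus the observed
#'   statistic in the `observed` column.
#' @exportS3Method generics::tidy
tidy.null_ensemble <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    replicate = seq_along(x$null_values),
    value = x$null_values,
    observed = x$observed
  )
}

#' @rdname tidy.null_ensemble
#' @return `glance()`: a one-row summary with `observed`, `null_mean`,
#'   `null_sd`, `z`, `p_value`, `replicates`.
#' @exportS3Method generics::glance
glance.null_ensemble <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed,
    null_mean = mean(x$null_values),
    null_sd = sd(x$null_values),
    z = x$z,
    p_value = x$p_value,
    replicates = length(x$null_values)
  )
}

#' Tidy a module partition
#'
#' @param x A `module_partition` from [maximize_modularity()].
#' @param ... Unused.
#' @return The node-to-module assignment tibble.
#' @exportS3Method generics::tidy
tidy.module_partition <- function(x, ...) x$modules

#' @rdname tidy.module_partition
#' @exportS3Method generics::glance
glance.module_partition <- function(x, ...) {
  tibble::tibble(Q = x$Q, n_modules = x$n_modules, n_nodes = nrow(x$modules))
}

#' Tidy an extinction result
#'
#' @param x An `extinction_result` from [robustness_suite()].
#' @param ... Unused.
#' @return The curve points of the directed scenarios, one row per step.
#' @exportS3Method generics::tidy
tidy.extinction_result <- function(x, ...) x$curves

#' @rdname tidy.extinction_result
#' @exportS3Method generics::glance
glance.extinction_result <- function(x, ...) x$summary
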