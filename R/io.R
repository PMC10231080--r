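#' Read an interaction matrix from disk
#'
#' Reads a quantitative bipartite interaction matrix in either of the two
#' conventional layouts: wide (first column = row labels, header = column
#' labels, integer cells; CSV or TSV by extension/sniffing) or a long edge
#' list with columns `hollow`, `species`, `count`. Orientation is normalized
#' so hollows are rows; zero rows/columns are dropped with a warning.
#'
#' @param path Path to a CSV/TSV file.
#' @param orientation For wide files: `"hollows_as_rows"` (default) or
#'   `"species_as_rows"` if the file stores species as rows.
#' @param format `"auto"` (default; a long file is recognized by its header),
#'   `"wide"` or `"long"`.
#' @param site,year Optional labels attached to the result.
#' @return An [interaction_matrix()].
#' @export
read_interaction_matrix <- function(path,
                                    orientation = c("hollows_as_rows", "species_as_rows"),
                                    format = c("auto", "wide", "long"),
                                    site = NULL, year = NULL) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  lower <- tolower(names(df))
  is_long <- format == "long" ||
    (format == "auto" && all(c("hollow", "species", "count") %in% lower))
  if (is_long) {
    names(df) <- lower
    return(interaction_matrix(df, site = site, year = year))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0(
        "Non-numeric cell at row '", df[[1]][bad[1, 1]], "', column '",
        colnames(m)[bad[1, 2]], "'."
      ))
    }
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- as.character(df[[1]])
  if (orientation == "species_as_rows") m <- t(m)
  interaction_matrix(m, site = site, year = year)
}

#' Write an interaction matrix to disk
#'
#' @param m An [interaction_matrix()].
#' @param path Output path; `.tsv` extension writes tab-separated.
#' @param format `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(m, path, format = c("wide", "long")) {
  format <- match.arg(format)
  m <- as_interaction(m)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  if (format == "long") {
    df <- as_tibble(m)[, c("hollow", "species", "count")]
  } else {
    df <- tibble::as_tibble(unclass_matrix(m), rownames = "hollow")
  }
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Write network summaries as a metric-by-network table
#'
#' Lays out one or more [network_summary()] rows in the conventional report
#' shape: metrics as rows, networks (site/year/scenario) as columns. The file
#' round-trips: [read_summary_table()] reproduces all values exactly.
#'
#' @param summaries A tibble of network summaries (rows from
#'   [network_summary()], typically with `site` and `year` columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0) {
    readr::write_csv(tibble::tibble(metric = character()), path)
    return(invisible(path))
  }
  id_cols <- intersect(c("site", "year", "scenario"), names(summaries))
  labels <- if (length(id_cols)) {
    apply(summaries[id_cols], 1, function(r) paste(r[!is.na(r)], collapse = "_"))
  } else {
    paste0("network_", seq_len(nrow(summaries)))
  }
  num <- summaries[vapply(summaries, is.numeric, logical(1))]
  mat <- t(as.matrix(num))
  colnames(mat) <- labels
  wide <- tibble::as_tibble(mat, rownames = "metric")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read back a summary table written by [write_summary_table()]
#'
#' @param path CSV path.
#' @return A tibble, metrics as rows and networks as columns.
#' @export
read_summary_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
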