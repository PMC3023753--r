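# Delimited-text readers/writers. Dialect: comma-separated, UTF-8,
# header row mandatory, "NA" for missing.

#' Read / write a plot-level phenotype table
#'
#' Columns: `clone`, `environment`, `replicate`, `trait`, `value`.
#' Unparseable `value` cells become missing with a logged count;
#' duplicated (clone, environment, replicate, trait) rows are an error.
#'
#' @param path File path.
#' @return A validated plot tibble.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
          class = "bruisemap_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  need <- c("clone", "environment", "replicate", "trait", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("plot table lacks required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "bruisemap_schema_error")
  }
  val <- suppressWarnings(as.numeric(raw$value))
  n_bad <- sum(is.na(val) & !is.na(raw$value))
  if (n_bad > 0) {
    inform(sprintf("%d unparseable value cell(s) set to missing.", n_bad))
  }
  raw$value <- val
  validate_plot_table(raw)
}

#' @rdname read_plot_table
#' @param plots Plot tibble.
#' @export
write_plot_table <- function(plots, path) {
  readr::write_csv(validate_plot_table(plots), path, na = "NA")
  invisible(path)
}

#' Read / write a marker matrix
#'
#' First column `clone`, remaining columns one fragment each with cells
#' 1 / 0 / NA.
#'
#' @param path File path.
#' @return A marker tibble (`clone` + integer fragment columns).
#' @export
read_marker_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
          class = "bruisemap_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  if (!"clone" %in% names(raw)) {
    abort("marker matrix lacks required column: clone.",
          class = "bruisemap_schema_error")
  }
  if (anyDuplicated(raw$clone)) {
    abort("duplicated clone rows in marker matrix.",
          class = "bruisemap_schema_error")
  }
  frag_cols <- setdiff(names(raw), "clone")
  n_bad <- 0L
  for (fc in frag_cols) {
    v <- suppressWarnings(as.integer(raw[[fc]]))
    bad <- (!is.na(raw[[fc]]) & is.na(v)) |
      (!is.na(v) & !v %in% c(0L, 1L))
    n_bad <- n_bad + sum(bad)
    v[bad] <- NA_integer_
    raw[[fc]] <- v
  }
  if (n_bad > 0) {
    inform(sprintf("%d unparseable marker cell(s) set to missing.",
                   n_bad))
  }
  as_tibble(raw)
}

#' @rdname read_marker_matrix
#' @param markers Marker tibble.
#' @export
write_marker_matrix <- function(markers, path) {
  as_marker_matrix(markers)  # validates
  readr::write_csv(as_tibble(markers), path, na = "NA")
  invisible(path)
}

#' Read / write fragment metadata (fragment, locus, chromosome)
#'
#' @param path File path.
#' @return Tibble with columns `fragment`, `locus`, `chromosome`.
#' @export
read_marker_metadata <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  need <- c("fragment", "locus", "chromosome")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("marker metadata lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "bruisemap_schema_error")
  }
  as_tibble(raw[need])
}

#' @rdname read_marker_metadata
#' @param metadata Metadata tibble.
#' @export
write_marker_metadata <- function(metadata, path) {
  readr::write_csv(as_tibble(metadata), path, na = "NA")
  invisible(path)
}

#' Write an association table (Table-3 style)
#'
#' @param records [scan_markers()] output.
#' @param path File path.
#' @export
write_association_table <- function(records, path) {
  readr::write_csv(as_tibble(records), path, na = "NA")
  invisible(path)
}
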