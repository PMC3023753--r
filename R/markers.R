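# Marker-panel container helpers. The user-facing representation is a
# wide tibble (one `clone` column plus one 0/1/NA column per fragment);
# numerical code works on the underlying integer matrix.

marker_tibble <- function(x) {
  stopifnot(is.matrix(x))
  out <- as_tibble(x, .name_repair = "minimal")
  dplyr::bind_cols(tibble(clone = rownames(x)), out)
}

#' Convert a marker tibble to a clones x fragments matrix
#'
#' @param markers A tibble with a `clone` column and one column of
#'   0/1/NA calls per fragment, or an already-formed numeric matrix with
#'   clone rownames.
#' @return Integer matrix, rows named by clone, columns by fragment.
#' @export
as_marker_matrix <- function(markers) {
  if (is.matrix(markers)) {
    storage.mode(markers) <- "integer"
    return(markers)
  }
  stopifnot(is.data.frame(markers), "clone" %in% names(markers))
  x <- as.matrix(markers[setdiff(names(markers), "clone")])
  storage.mode(x) <- "integer"
  bad <- x[!is.na(x)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    abort("marker calls must be 0, 1 or NA.",
          class = "bruisemap_schema_error")
  }
  rownames(x) <- as.character(markers$clone)
  if (anyDuplicated(colnames(x))) {
    abort("fragment names must be unique.",
          class = "bruisemap_schema_error")
  }
  x
}

#' Fragment presence frequency
#'
#' Percentage of clones with a non-missing call that carry the
#' fragment, as reported in association output ("Fr. (%)").
#'
#' @param markers Marker tibble or matrix.
#' @param fragment Fragment (column) name.
#' @return A single percentage in [0, 100].
#' @export
#' @examples
#' m <- tibble::tibble(clone = letters[1:4], f1 = c(1, 0, NA, 1))
#' allele_frequency(m, "f1")
allele_frequency <- function(markers, fragment) {
  x <- as_marker_matrix(markers)
  if (!fragment %in% colnames(x)) {
    abort(sprintf("fragment '%s' not found.", fragment),
          class = "bruisemap_schema_error")
  }
  calls <- x[, fragment]
  n_ok <- sum(!is.na(calls))
  if (n_ok == 0L) {
    abort(sprintf("fragment '%s' has no non-missing calls.", fragment),
          class = "bruisemap_domain_error")
  }
  100 * sum(calls, na.rm = TRUE) / n_ok
}
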