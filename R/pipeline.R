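#' Configuration for the end-to-end association pipeline
#'
#' @param traits Traits to analyse (rows of the plot table); SCB is
#'   derived automatically when both `bi_trait` and `sg_trait` are
#'   present and `derive_scb = TRUE`.
#' @param bi_trait,sg_trait,scb_trait Trait labels used for the
#'   starch-corrected-bruising derivation.
#' @param derive_scb Append SCB (residual of BI on SG) before stage 1.
#' @param h2_variant Heritability formula variant, see
#'   [estimate_heritability()].
#' @param kinship_estimator Passed to [kinship_matrix()].
#' @param target_variance Cumulative explained-variance target for the
#'   number of structure axes, see [pcoa_structure()].
#' @param p_report,p_highlight Reporting thresholds for the scan
#'   (records kept below `p_report`; `p_highlight` marks the
#'   highly-significant tier).
#' @param p_enter P-to-enter criterion of the forward selection.
#' @param min_count Minimum carriers / non-carriers per testable
#'   fragment.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param output_dir Optional directory: result tables are written as
#'   CSV (plus a JSON manifest) when given.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(traits = c("BI", "SG"),
                            bi_trait = "BI", sg_trait = "SG",
                            scb_trait = "SCB", derive_scb = TRUE,
                            h2_variant = "standard",
                            kinship_estimator = "loiselle",
                            target_variance = 0.25,
                            p_report = 0.01, p_highlight = 0.001,
                            p_enter = 0.001, min_count = 5,
                            seed = 1L, output_dir = NULL) {
  for (p in c(p_report, p_highlight, p_enter)) {
    check_fraction(p, "p threshold", lo = 0, hi = 1, lo_open = TRUE,
                   hi_open = TRUE)
  }
  structure(list(
    traits = as.character(traits), bi_trait = bi_trait,
    sg_trait = sg_trait, scb_trait = scb_trait,
    derive_scb = isTRUE(derive_scb), h2_variant = h2_variant,
    kinship_estimator = kinship_estimator,
    target_variance = target_variance, p_report = p_report,
    p_highlight = p_highlight, p_enter = p_enter,
    min_count = check_count(min_count, "min_count", min = 1L),
    seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

#' Run the full two-stage association pipeline
#'
#' Composes the whole analysis: SCB derivation, stage-one REML variance
#' components, heritabilities and adjusted entry means per trait, trait
#' correlations, kinship and principal-coordinate structure, the
#' single-marker PK scan and the multi-locus forward selection per
#' trait, plus a run manifest recording the configuration, seed,
#' package version and every exclusion count. Identical config and
#' inputs give identical outputs.
#'
#' @param plots Plot table (tibble or path to CSV).
#' @param markers Marker matrix (tibble or path to CSV).
#' @param metadata Optional fragment metadata (tibble or path).
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `variance_components`,
#'   `heritability`, `entry_means`, `correlations`, `kinship`,
#'   `structure`, `associations`, `forward_selection`, `manifest`.
#' @export
run_pipeline <- function(plots, markers, metadata = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(plots)) plots <- read_plot_table(plots)
  if (is.character(markers)) markers <- read_marker_matrix(markers)
  if (is.character(metadata)) metadata <- read_marker_metadata(metadata)
  plots <- validate_plot_table(plots)
  x <- as_marker_matrix(markers)

  manifest <- list(
    config = unclass(config)[setdiff(names(config), "output_dir")],
    seed = config$seed,
    package_version = as.character(packageVersion("bruisemap")),
    n_plot_rows = nrow(plots),
    n_marker_clones = nrow(x),
    n_fragments = ncol(x)
  )

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "bruisemap_pipeline_error", parent = e)
    })
  }

  traits <- config$traits
  if (config$derive_scb &&
      all(c(config$bi_trait, config$sg_trait) %in% plots$trait)) {
    plots <- stage("derive_scb",
                   compute_scb(plots, config$bi_trait, config$sg_trait,
                               config$scb_trait))
    traits <- union(traits, config$scb_trait)
  }
  traits <- intersect(traits, unique(plots$trait))
  if (!length(traits)) {
    abort("none of the configured traits occur in the plot table.",
          class = "bruisemap_insufficient_data")
  }

  vcs <- list(); h2s <- list(); means <- list()
  for (tr in traits) {
    vcs[[tr]] <- stage(paste0("fit_plot_model:", tr),
                       fit_plot_model(plots, tr))
    means[[tr]] <- stage(paste0("adjusted_entry_means:", tr),
                         adjusted_entry_means(plots, tr, vcs[[tr]]))
    h2s[[tr]] <- stage(paste0("heritability:", tr),
                       estimate_heritability(vcs[[tr]], means[[tr]],
                                             variant = config$h2_variant))
  }
  correlations <- if (length(traits) > 1L) {
    stage("trait_correlations", trait_correlations(means))
  } else {
    NULL
  }

  pheno_clones <- unique(plots$clone)
  shared <- intersect(rownames(x), pheno_clones)
  manifest$n_marker_only_clones <- nrow(x) - length(shared)
  if (manifest$n_marker_only_clones > 0) {
    inform(sprintf("%d marker clone(s) absent from phenotypes dropped.",
                   manifest$n_marker_only_clones))
  }
  xs <- marker_tibble(x[shared, , drop = FALSE])

  kin <- stage("kinship", kinship_matrix(xs,
                                         estimator = config$kinship_estimator))
  pco <- stage("pcoa", pcoa_structure(xs,
                                      target_variance = config$target_variance))

  associations <- list(); forward <- list()
  for (tr in traits) {
    associations[[tr]] <- stage(paste0("scan:", tr),
      scan_markers(means[[tr]], kin, pco, xs,
                   p_threshold = config$p_report,
                   min_count = config$min_count, metadata = metadata))
    forward[[tr]] <- stage(paste0("forward:", tr),
      forward_select(means[[tr]], kin, pco, xs,
                     p_enter = config$p_enter,
                     min_count = config$min_count))
  }

  assoc_tbl <- purrr::list_rbind(purrr::map(associations, as_tibble)) |>
    mutate(highlight = .data$p_value < config$p_highlight)
  manifest$n_skipped_fragments <- purrr::map_int(
    associations, ~ nrow(attr(.x, "skipped")))
  manifest$n_associations_reported <- nrow(assoc_tbl)
  manifest$q_structure_axes <- pco$q

  fwd_tbl <- purrr::list_rbind(purrr::imap(forward, function(f, tr) {
    tibble(trait = tr,
           fragments = paste(f$steps$fragment, collapse = ";"),
           n_selected = nrow(f$steps),
           explained_genetic_variance = f$explained_genetic_variance)
  }))

  result <- structure(list(
    variance_components = purrr::list_rbind(purrr::imap(vcs,
      ~ mutate(tidy(.x), trait = .y))),
    heritability = purrr::list_rbind(h2s),
    entry_means = purrr::list_rbind(purrr::map(means, as_tibble)),
    correlations = correlations,
    kinship = kin,
    structure = pco,
    associations = assoc_tbl,
    association_details = associations,
    forward_selection = fwd_tbl,
    forward_details = forward,
    manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE,
               showWarnings = FALSE)
    outp <- function(f) file.path(config$output_dir, f)
    readr::write_csv(result$variance_components,
                     outp("variance_components.csv"), na = "NA")
    readr::write_csv(result$heritability, outp("heritability.csv"),
                     na = "NA")
    readr::write_csv(result$entry_means, outp("entry_means.csv"),
                     na = "NA")
    if (!is.null(result$correlations)) {
      readr::write_csv(result$correlations, outp("correlations.csv"),
                       na = "NA")
    }
    readr::write_csv(result$associations, outp("associations.csv"),
                     na = "NA")
    readr::write_csv(result$forward_selection,
                     outp("forward_selection.csv"), na = "NA")
    utils::write.csv(unclass(kin), outp("kinship.csv"))
    readr::write_csv(pco$scores, outp("structure.csv"), na = "NA")
    jsonlite::write_json(manifest, outp("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Two-stage PK association pipeline result\n")
  cat(sprintf("  traits: %s\n",
              paste(unique(x$heritability$trait), collapse = ", ")))
  cat(sprintf("  structure axes q = %d; %d association record(s) reported\n",
              x$structure$q, nrow(x$associations)))
  invisible(x)
}
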