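#' Bruising index from discoloration category counts
#'
#' Scores a plot's bruising severity on a 0-100 scale from tuber counts
#' in the four visual discoloration categories. With `L`, `M`, `S` the
#' fractions of tubers showing light, medium and strong discoloration,
#' the index is `BI = (0.3 L + 0.5 M + S) * 100`, ranging from 0 (no
#' tuber discolored) to 100 (all tubers strongly discolored).
#'
#' @param counts A data frame with columns `n_none`, `n_light`,
#'   `n_medium`, `n_strong` (one row per plot).
#' @return A tibble: the input plus a `bi` column.
#' @export
#' @examples
#' compute_bruising_index(
#'   tibble::tibble(n_none = 0, n_light = 3, n_medium = 2, n_strong = 5)
#' )
compute_bruising_index <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("n_none", "n_light", "n_medium", "n_strong")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(sprintf("`counts` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "bruisemap_schema_error")
  }
  cts <- as.matrix(counts[need])
  if (any(cts < 0, na.rm = TRUE)) {
    abort("category counts must be non-negative.",
          class = "bruisemap_domain_error")
  }
  total <- rowSums(cts)
  if (any(total <= 0, na.rm = TRUE)) {
    abort("total tuber count must be positive in every plot.",
          class = "bruisemap_domain_error")
  }
  counts$bi <- unname(100 * (0.3 * cts[, "n_light"] +
                               0.5 * cts[, "n_medium"] +
                               cts[, "n_strong"]) / total)
  counts
}

#' Append starch-corrected bruising (SCB) to a plot table
#'
#' SCB decouples bruising from starch content: it is the residual of
#' the ordinary least-squares regression of the bruising index (BI) on
#' specific gravity (SG), fitted jointly across all paired plot
#' observations. Residuals are mean-zero and exactly orthogonal to SG.
#'
#' @param plots Plot table (long): columns `clone`, `environment`,
#'   `replicate`, `trait`, `value`, containing BI and SG rows.
#' @param bi_trait,sg_trait Trait labels of the index and of specific
#'   gravity.
#' @param scb_trait Label for the appended residual trait.
#' @return The plot table with SCB rows appended.
#' @export
compute_scb <- function(plots, bi_trait = "BI", sg_trait = "SG",
                        scb_trait = "SCB") {
  plots <- validate_plot_table(plots)
  wide <- plots |>
    filter(.data$trait %in% c(bi_trait, sg_trait)) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  wide <- wide[complete.cases(wide[c(bi_trait, sg_trait)]), ]
  if (nrow(wide) < 3L) {
    abort("need at least 3 paired BI/SG observations.",
          class = "bruisemap_insufficient_data")
  }
  if (sd(wide[[sg_trait]]) == 0) {
    abort("specific gravity is constant; SCB regression is degenerate.",
          class = "bruisemap_degenerate_error")
  }
  fit <- lm(wide[[bi_trait]] ~ wide[[sg_trait]])
  scb <- wide |>
    select("clone", "environment", "replicate") |>
    mutate(trait = scb_trait, value = as.numeric(resid(fit)))
  bind_rows(plots, scb)
}

#' Validate (and coerce) a plot-level phenotype table
#'
#' @param plots Data frame with columns `clone`, `environment`,
#'   `replicate`, `trait`, `value`.
#' @return The table as a tibble with character keys.
#' @export
validate_plot_table <- function(plots) {
  plots <- as_tibble(plots)
  need <- c("clone", "environment", "replicate", "trait", "value")
  missing_cols <- setdiff(need, names(plots))
  if (length(missing_cols)) {
    abort(sprintf("plot table lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "bruisemap_schema_error")
  }
  plots <- plots |>
    mutate(across(c("clone", "environment", "replicate", "trait"),
                  as.character),
           value = as.numeric(.data$value))
  dup <- plots |>
    dplyr::count(.data$clone, .data$environment, .data$replicate,
                 .data$trait) |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicated (clone, environment, replicate, trait) rows, e.g. (%s).",
      paste(unlist(dup[1, 1:4]), collapse = ", ")),
      class = "bruisemap_schema_error")
  }
  plots[need]
}

#' Fit the all-random multi-environment plot model by REML
#'
#' Stage one of the two-stage analysis. For one trait, fits
#' `y_ijk = mu + g_i + l_j + (gl)_ij + r_jk + e_ijk` with genotype,
#' environment, genotype x environment and replicate-within-environment
#' all random, and returns the five REML variance components
#' (constrained non-negative) with the restricted log-likelihood.
#'
#' @param plots Plot table (long format, see
#'   [validate_plot_table()]).
#' @param trait Trait to analyse.
#' @return An object of class `plot_model_fit`: list with `vc` (named
#'   variance components), `loglik`, `n_obs`, `trait`, `data` (the rows
#'   used) and the underlying `lme4` fit.
#' @export
fit_plot_model <- function(plots, trait) {
  plots <- validate_plot_table(plots)
  d <- filter(plots, .data$trait == !!trait, !is.na(.data$value))
  if (nrow(d) == 0L) {
    abort(sprintf("no observations for trait '%s'.", trait),
          class = "bruisemap_insufficient_data")
  }
  n_env <- dplyr::n_distinct(d$environment)
  n_rep <- d |>
    dplyr::count(.data$clone, .data$environment) |>
    pull(.data$n) |>
    max()
  if (n_env < 2L && n_rep < 2L) {
    abort(paste("non-identifiable design: a single environment and a",
                "single replicate confound (genotype, residual) and",
                "(environment, intercept)."),
          class = "bruisemap_identifiability_error")
  }
  if (n_env < 2L) {
    abort(paste("non-identifiable design: one environment confounds",
                "(environment, intercept) and (GxE, genotype)."),
          class = "bruisemap_identifiability_error")
  }
  if (dplyr::n_distinct(d$clone) < 2L) {
    abort("need at least 2 clones.",
          class = "bruisemap_insufficient_data")
  }

  d <- d |>
    mutate(
      gxe = paste(.data$clone, .data$environment, sep = ":"),
      env_rep = paste(.data$environment, .data$replicate, sep = ":")
    )

  comp_names <- c("sigma2_g", "sigma2_env", "sigma2_gxe", "sigma2_rep",
                  "sigma2_e")
  if (var(d$value) == 0) {
    # degenerate but exact: constant response, all components zero
    vc <- setNames(numeric(5L), comp_names)
    out <- structure(
      list(vc = vc, loglik = reml_loglik_plot(d, vc), n_obs = nrow(d),
           trait = trait, data = d, fit = NULL),
      class = "plot_model_fit")
    return(out)
  }

  fit <- suppressMessages(lme4::lmer(
    value ~ 1 + (1 | clone) + (1 | environment) + (1 | gxe) +
      (1 | env_rep),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.nlev.gtr.1 = "ignore",
                                calc.derivs = FALSE)))
  vcd <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vcd$vcov[vcd$grp == g]
    if (length(v)) v else 0
  }
  vc <- setNames(c(getv("clone"), getv("environment"), getv("gxe"),
                   getv("env_rep"), getv("Residual")), comp_names)
  structure(
    list(vc = vc, loglik = as.numeric(logLik(fit)), n_obs = nrow(d),
         trait = trait, data = d, fit = fit),
    class = "plot_model_fit")
}

# Restricted log-likelihood of the plot model at given variance
# components, by direct dense-V evaluation (X = intercept only). Used
# for degenerate fits and as the common yardstick for the grid oracle.
reml_loglik_plot <- function(d, vc, floor_e = 1e-10) {
  y <- d$value
  n <- length(y)
  zmat <- function(f) {
    f <- factor(f)
    stats::model.matrix(~ 0 + f)
  }
  v <- diag(max(vc[["sigma2_e"]], floor_e), n)
  if (vc[["sigma2_g"]] > 0) {
    z <- zmat(d$clone); v <- v + vc[["sigma2_g"]] * tcrossprod(z)
  }
  if (vc[["sigma2_env"]] > 0) {
    z <- zmat(d$environment); v <- v + vc[["sigma2_env"]] * tcrossprod(z)
  }
  if (vc[["sigma2_gxe"]] > 0) {
    z <- zmat(paste(d$clone, d$environment, sep = ":"))
    v <- v + vc[["sigma2_gxe"]] * tcrossprod(z)
  }
  if (vc[["sigma2_rep"]] > 0) {
    z <- zmat(paste(d$environment, d$replicate, sep = ":"))
    v <- v + vc[["sigma2_rep"]] * tcrossprod(z)
  }
  x <- matrix(1, n, 1L)
  reml_loglik_dense(y, x, v)
}

# Generic dense restricted log-likelihood for y ~ N(X b, V).
reml_loglik_dense <- function(y, x, v) {
  n <- length(y)
  p <- ncol(x)
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet_v <- 2 * sum(log(diag(ch)))
  vi_x <- backsolve(ch, forwardsolve(t(ch), x))
  vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  xtvx <- crossprod(x, vi_x)
  b <- solve(xtvx, crossprod(x, vi_y))
  r <- y - x %*% b
  vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- sum(r * vi_r)
  -0.5 * (logdet_v + determinant(xtvx, logarithm = TRUE)$modulus[1] +
            quad + (n - p) * log(2 * pi))
}

#' Entry-mean heritability
#'
#' Broad-sense heritability on an entry-mean basis:
#' `h2 = sigma2_g / (sigma2_g + wbar / 2)`, with `wbar` the mean
#' variance of a difference between two adjusted entry means. The
#' `"plabstat"` variant uses `sigma2_g / (sigma2_g + wbar)`.
#'
#' @param vc A [fit_plot_model()] result (or a list with a named `vc`
#'   vector containing `sigma2_g`).
#' @param means An [adjusted_entry_means()] result (supplies `wbar`).
#' @param variant `"standard"` (half the mean variance of a difference)
#'   or `"plabstat"`.
#' @return A tibble with `trait`, `h2`, `sigma2_g`, `wbar`, `variant`.
#' @export
estimate_heritability <- function(vc, means, variant = c("standard",
                                                         "plabstat")) {
  variant <- match.arg(variant)
  s2g <- vc$vc[["sigma2_g"]]
  wbar <- attr(means, "wbar")
  if (is.null(wbar) || !is.finite(wbar) || wbar <= 0) {
    abort("`means` carries no positive mean variance of a difference.",
          class = "bruisemap_degenerate_error")
  }
  denom <- if (variant == "standard") s2g + wbar / 2 else s2g + wbar
  h2 <- if (denom <= 0) 0 else s2g / denom
  tibble(
    trait = vc$trait %||% attr(means, "trait") %||% NA_character_,
    h2 = min(max(h2, 0), 1),
    sigma2_g = s2g, wbar = wbar, variant = variant
  )
}

#' Correlations between adjusted entry means of several traits
#'
#' Pairwise Pearson correlations over the clones present in both
#' traits, with two-sided p-values and significance stars
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise).
#'
#' @param means_by_trait A named list of [adjusted_entry_means()]
#'   results, or a single tibble with columns `clone`, `trait`,
#'   `estimate`.
#' @return A tibble: `trait_x`, `trait_y`, `r`, `p_value`, `stars`,
#'   `n`.
#' @export
trait_correlations <- function(means_by_trait) {
  if (is.data.frame(means_by_trait)) {
    tbl <- as_tibble(means_by_trait)
  } else {
    tbl <- purrr::list_rbind(purrr::imap(means_by_trait, function(m, nm) {
      m <- as_tibble(m)
      if (!"trait" %in% names(m) || all(is.na(m$trait))) m$trait <- nm
      m
    }))
  }
  stopifnot(all(c("clone", "trait", "estimate") %in% names(tbl)))
  traits <- unique(tbl$trait)
  pairs <- tidyr::expand_grid(trait_x = traits, trait_y = traits)
  out <- purrr::pmap(pairs, function(trait_x, trait_y) {
    a <- filter(tbl, .data$trait == trait_x, !is.na(.data$estimate))
    b <- filter(tbl, .data$trait == trait_y, !is.na(.data$estimate))
    shared <- intersect(a$clone, b$clone)
    if (length(shared) < 3L) {
      abort(sprintf("fewer than 3 clones shared by '%s' and '%s'.",
                    trait_x, trait_y),
            class = "bruisemap_insufficient_data")
    }
    xa <- a$estimate[match(shared, a$clone)]
    xb <- b$estimate[match(shared, b$clone)]
    if (identical(trait_x, trait_y)) {
      r <- 1; p <- 0
    } else {
      ct <- cor.test(xa, xb)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    tibble(trait_x = trait_x, trait_y = trait_y, r = r, p_value = p,
           stars = p_stars(p), n = length(shared))
  })
  purrr::list_rbind(out)
}
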