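#' Configuration for the synthetic tetraploid trial generator
#'
#' Bundles every knob of the synthetic-data generator: the marker panel
#' (dominant presence/absence fragments with optional subpopulation
#' structure and admixture), the multi-environment trial design, the
#' variance components of the plot model, and planted QTL effects. The
#' defaults emulate the study design the package targets: 205 tetraploid
#' clones scored for 362 dominant fragments and evaluated in 6
#' environments (year x location) with 2 replicates each.
#'
#' @param n_clones Number of clones (entries) in the panel.
#' @param n_markers Number of dominant-scored DNA fragments.
#' @param n_subpops Number of latent subpopulations the fragment
#'   frequencies are drawn for. `1` gives a panmictic panel.
#' @param admixture_concentration Dirichlet concentration of per-clone
#'   admixture proportions; small values give near-pure membership.
#' @param fst Balding-Nichols divergence of subpopulation fragment
#'   frequencies around their ancestral value (ignored when
#'   `n_subpops = 1`).
#' @param n_environments,n_replicates Trial dimensions; each environment
#'   is a year x location combination, replicates are nested within
#'   environments.
#' @param sigma2_g,sigma2_env,sigma2_gxe,sigma2_rep,sigma2_e Variance
#'   components on the trait scale: genotype, environment, genotype x
#'   environment, replicate within environment, and plot residual.
#' @param qtl_spec Planted QTL effects: a two-column data frame (or
#'   tibble) with `marker` (integer index into the panel) and `effect`
#'   (additive effect in trait units of carrying the fragment), or
#'   `NULL` for none.
#' @param polygenic_h2_share Fraction of `sigma2_g` carried by the
#'   kinship-structured polygenic term. Planted QTL effects are kept
#'   literal in trait units on top of it, so with a non-empty
#'   `qtl_spec` the total genetic variance is
#'   `polygenic_h2_share * sigma2_g` plus the realized QTL variance.
#' @param missing_rate Fraction of marker calls set to missing.
#' @param n_tubers_per_plot Tubers examined per plot when bruising
#'   category counts are generated.
#' @param mu Trait intercept.
#' @param trait Trait label written into simulated plot tables.
#' @param seed Integer seed; the same config reproduces identical data.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_markers()], [simulate_trial()],
#'   [simulate_bruising_counts()]
#' @export
#' @examples
#' cfg <- sim_config(n_clones = 20, n_markers = 30, n_environments = 2)
#' sim <- simulate_markers(cfg)
#' dim(sim$markers)
sim_config <- function(n_clones = 205,
                       n_markers = 362,
                       n_subpops = 1,
                       admixture_concentration = 1,
                       fst = 0.15,
                       n_environments = 6,
                       n_replicates = 2,
                       sigma2_g = 100,
                       sigma2_env = 50,
                       sigma2_gxe = 30,
                       sigma2_rep = 10,
                       sigma2_e = 40,
                       qtl_spec = NULL,
                       polygenic_h2_share = 1,
                       missing_rate = 0.05,
                       n_tubers_per_plot = 100,
                       mu = 25,
                       trait = "BI",
                       seed = 1L) {
  cfg <- list(
    n_clones = check_count(n_clones, "n_clones"),
    n_markers = check_count(n_markers, "n_markers"),
    n_subpops = check_count(n_subpops, "n_subpops"),
    admixture_concentration = check_fraction(admixture_concentration,
      "admixture_concentration", lo = 0, hi = Inf, lo_open = TRUE),
    fst = check_fraction(fst, "fst", lo = 0, hi = 1, lo_open = TRUE,
                         hi_open = TRUE),
    n_environments = check_count(n_environments, "n_environments"),
    n_replicates = check_count(n_replicates, "n_replicates"),
    sigma2_g = check_nonneg(sigma2_g, "sigma2_g"),
    sigma2_env = check_nonneg(sigma2_env, "sigma2_env"),
    sigma2_gxe = check_nonneg(sigma2_gxe, "sigma2_gxe"),
    sigma2_rep = check_nonneg(sigma2_rep, "sigma2_rep"),
    sigma2_e = check_nonneg(sigma2_e, "sigma2_e"),
    qtl_spec = qtl_spec,
    polygenic_h2_share = check_fraction(polygenic_h2_share,
                                        "polygenic_h2_share"),
    missing_rate = check_fraction(missing_rate, "missing_rate",
                                  hi_open = TRUE),
    n_tubers_per_plot = check_count(n_tubers_per_plot,
                                    "n_tubers_per_plot"),
    mu = as.numeric(mu),
    trait = as.character(trait),
    seed = as.integer(seed)
  )
  if (!is.null(cfg$qtl_spec)) {
    qs <- as_tibble(cfg$qtl_spec)
    if (!all(c("marker", "effect") %in% names(qs))) {
      abort("`qtl_spec` needs columns `marker` and `effect`.",
            class = "bruisemap_invalid_config")
    }
    if (any(qs$marker < 1 | qs$marker > cfg$n_markers)) {
      abort("`qtl_spec$marker` indices must lie in [1, n_markers].",
            class = "bruisemap_invalid_config")
    }
    cfg$qtl_spec <- qs
  }
  structure(cfg, class = "sim_config")
}

clone_ids <- function(n) sprintf("CL%03d", seq_len(n))
fragment_ids <- function(n) sprintf("frag%03d", seq_len(n))

#' Simulate a dominant marker panel with population structure
#'
#' Draws per-subpopulation fragment presence frequencies under a
#' Balding-Nichols model around ancestral frequencies, per-clone
#' admixture proportions from a symmetric Dirichlet, and scores each
#' fragment as present (1) / absent (0) with the admixture-weighted
#' frequency; a `missing_rate` fraction of calls is masked. With
#' `n_subpops = 1` the panel is panmictic.
#'
#' The returned truth records the generating presence probabilities, the
#' admixture matrix, hard subpopulation labels (largest admixture
#' share), and the generating kinship: the same moment form the
#' estimator uses, evaluated on the generating probabilities instead of
#' the realized calls (off-diagonals untruncated, diagonal 1).
#'
#' @param config A [sim_config()].
#' @return A list with `markers` (tibble: `clone` plus one 0/1/NA column
#'   per fragment), `metadata` (tibble: fragment, locus, chromosome),
#'   and `truth` (list: `freqs`, `admixture`, `subpop`, `kinship`,
#'   `presence_prob`).
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_clones
  m <- config$n_markers
  with_seed(config$seed, {
    p_anc <- runif(m, 0.1, 0.9)
    if (config$n_subpops == 1L) {
      p_sub <- matrix(p_anc, nrow = 1L)
      q_adm <- matrix(1, n, 1L)
    } else {
      f <- config$fst
      shape_scale <- (1 - f) / f
      p_sub <- t(vapply(seq_len(config$n_subpops), function(s) {
        rbeta(m, p_anc * shape_scale, (1 - p_anc) * shape_scale)
      }, numeric(m)))
      g <- matrix(stats::rgamma(n * config$n_subpops,
                                shape = config$admixture_concentration),
                  nrow = n)
      # at very small concentration all gamma draws in a row can
      # underflow to zero; the limiting Dirichlet is a one-hot draw
      bad <- !is.finite(rowSums(g)) | rowSums(g) <= 0
      if (any(bad)) {
        for (i in which(bad)) {
          g[i, ] <- 0
          g[i, sample.int(config$n_subpops, 1L)] <- 1
        }
      }
      q_adm <- g / rowSums(g)
    }
    # presence probability per clone x fragment (clamped: the dot
    # product can exceed [0,1] by a rounding ulp)
    prob <- pmin(pmax(q_adm %*% p_sub, 0), 1)
    x <- matrix(rbinom(n * m, 1L, as.vector(prob)), n, m)
    if (config$missing_rate > 0) {
      miss <- matrix(runif(n * m) < config$missing_rate, n, m)
      x[miss] <- NA_integer_
    }
    dimnames(x) <- list(clone_ids(n), fragment_ids(m))

    truth <- list(
      freqs = p_sub,
      admixture = q_adm,
      subpop = max.col(q_adm, ties.method = "first"),
      kinship = generating_kinship(prob),
      presence_prob = prob
    )
    list(
      markers = marker_tibble(x),
      metadata = tibble(
        fragment = colnames(x),
        locus = sprintf("locus%02d", ((seq_len(m) - 1L) %/% 4L) + 1L),
        chromosome = as.character(((seq_len(m) - 1L) %% 12L) + 1L)
      ),
      truth = truth
    )
  })
}

# Loiselle-form kinship evaluated on generating presence probabilities:
# the noiseless analogue of the estimator, untruncated off-diagonals.
generating_kinship <- function(prob) {
  pbar <- colMeans(prob)
  keep <- pbar > 0 & pbar < 1
  z <- sweep(prob[, keep, drop = FALSE], 2L, pbar[keep])
  denom <- sum(pbar[keep] * (1 - pbar[keep]))
  k <- tcrossprod(z) / denom
  diag(k) <- 1
  dimnames(k) <- list(rownames(prob), rownames(prob))
  k
}

#' Simulate a multi-environment replicated plot trial
#'
#' Generates plot values under the all-random model
#' `y_ijk = mu + g_i + l_j + (gl)_ij + r_jk + e_ijk` for every clone x
#' environment x replicate cell. The genetic value `g_i` is the sum of
#' planted QTL contributions (fragment code times effect, missing calls
#' imputed at the fragment frequency) and a polygenic term drawn from
#' `MVN(0, 2 * K_true * sigma2_u)` with `sigma2_u` scaled so its
#' marginal variance equals `polygenic_h2_share * sigma2_g`.
#' Environment, G x E, replicate-within-environment and plot residual
#' effects are drawn independently with the configured variances.
#'
#' @param markers Result of [simulate_markers()], or a marker tibble.
#' @param config The same [sim_config()].
#' @param truth Truth list from [simulate_markers()]; required when
#'   `markers` is a bare tibble.
#' @return A list with `plots` (tibble: clone, environment, replicate,
#'   trait, value) and `truth` (genetic values, realized effects, the
#'   generating variance components).
#' @export
simulate_trial <- function(markers, config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(markers) && !is.data.frame(markers) &&
      !is.null(markers$markers)) {
    truth <- truth %||% markers$truth
    markers <- markers$markers
  }
  x <- as_marker_matrix(markers)
  if (nrow(x) != config$n_clones) {
    abort("marker matrix row count must equal `n_clones`.",
          class = "bruisemap_invalid_config")
  }
  n <- config$n_clones
  k_true <- truth$kinship %||% diag(n)

  with_seed(config$seed + 1L, {
    # planted QTL contribution, literal trait units
    g_qtl <- numeric(n)
    if (!is.null(config$qtl_spec) && nrow(config$qtl_spec) > 0) {
      for (r in seq_len(nrow(config$qtl_spec))) {
        xm <- x[, config$qtl_spec$marker[r]]
        fr <- mean(xm, na.rm = TRUE)
        if (is.nan(fr) || fr %in% c(0, 1)) {
          warn(sprintf(
            "QTL planted on monomorphic marker %d: effect unidentifiable.",
            config$qtl_spec$marker[r]))
          fr <- ifelse(is.nan(fr), 0, fr)
        }
        xm[is.na(xm)] <- fr
        g_qtl <- g_qtl + config$qtl_spec$effect[r] * xm
      }
    }
    # polygenic part: covariance proportional to the generating kinship
    s2_poly <- config$polygenic_h2_share * config$sigma2_g
    g_poly <- numeric(n)
    if (s2_poly > 0) {
      cov2k <- 2 * k_true
      s2_u <- s2_poly / mean(diag(cov2k))
      ev <- eigen(cov2k, symmetric = TRUE)
      lam <- pmax(ev$values, 0)
      g_poly <- as.vector(ev$vectors %*% (sqrt(lam * s2_u) * rnorm(n)))
    }
    g <- g_qtl + g_poly

    env <- sprintf("E%d", seq_len(config$n_environments))
    l_j <- rnorm(config$n_environments, 0, sqrt(config$sigma2_env))
    design <- tidyr::expand_grid(
      clone = rownames(x),
      environment = env,
      replicate = sprintf("R%d", seq_len(config$n_replicates))
    )
    gl <- matrix(rnorm(n * config$n_environments, 0,
                       sqrt(config$sigma2_gxe)),
                 n, config$n_environments,
                 dimnames = list(rownames(x), env))
    r_jk <- matrix(rnorm(config$n_environments * config$n_replicates, 0,
                         sqrt(config$sigma2_rep)),
                   config$n_environments, config$n_replicates,
                   dimnames = list(env, sprintf("R%d",
                     seq_len(config$n_replicates))))
    ii <- match(design$clone, rownames(x))
    jj <- match(design$environment, env)
    kk <- match(design$replicate, colnames(r_jk))
    value <- config$mu + g[ii] + l_j[jj] + gl[cbind(ii, jj)] +
      r_jk[cbind(jj, kk)] +
      rnorm(nrow(design), 0, sqrt(config$sigma2_e))

    plots <- design |>
      mutate(trait = config$trait, value = value) |>
      select("clone", "environment", "replicate", "trait", "value")

    list(
      plots = plots,
      truth = list(
        genetic_values = setNames(g, rownames(x)),
        qtl_values = setNames(g_qtl, rownames(x)),
        polygenic_values = setNames(g_poly, rownames(x)),
        env_effects = setNames(l_j, env),
        variance_components = c(
          sigma2_g = config$sigma2_g, sigma2_env = config$sigma2_env,
          sigma2_gxe = config$sigma2_gxe, sigma2_rep = config$sigma2_rep,
          sigma2_e = config$sigma2_e),
        qtl_spec = config$qtl_spec
      )
    )
  })
}

#' Draw per-plot bruising category counts around a latent index
#'
#' Converts a latent bruising index in [0, 100] into tuber counts over
#' the four visual categories (none / light / medium / strong, BI
#' weights 0, 0.3, 0.5, 1). All probability mass is placed on the two
#' categories whose weights bracket `latent_bi / 100`, split so the
#' expected recomputed index equals `latent_bi` exactly.
#'
#' @param latent_bi Latent index values in [0, 100] (vectorized).
#' @param n_tubers Tubers examined per plot.
#' @param seed Integer seed.
#' @return A tibble with columns `n_none`, `n_light`, `n_medium`,
#'   `n_strong`, one row per element of `latent_bi`.
#' @export
#' @examples
#' simulate_bruising_counts(c(0, 50, 100), n_tubers = 10, seed = 1)
simulate_bruising_counts <- function(latent_bi, n_tubers, seed = 1L) {
  if (any(!is.finite(latent_bi)) || any(latent_bi < 0 | latent_bi > 100)) {
    abort("`latent_bi` must lie in [0, 100].",
          class = "bruisemap_domain_error")
  }
  n_tubers <- check_count(n_tubers, "n_tubers")
  w <- c(0, 0.3, 0.5, 1)
  with_seed(seed, {
    counts <- vapply(latent_bi / 100, function(b) {
      hi <- which(w >= b)[1]
      lo <- max(which(w <= b))
      pr <- numeric(4L)
      if (lo == hi) {
        pr[lo] <- 1
      } else {
        pr[hi] <- (b - w[lo]) / (w[hi] - w[lo])
        pr[lo] <- 1 - pr[hi]
      }
      as.numeric(rmultinom(1L, n_tubers, pr))
    }, numeric(4L))
    tibble(
      n_none = counts[1L, ], n_light = counts[2L, ],
      n_medium = counts[3L, ], n_strong = counts[4L, ]
    )
  })
}

#' Write a simulation truth object as JSON
#'
#' @param truth Truth list from [simulate_markers()] or
#'   [simulate_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE, force = TRUE)
  invisible(path)
}
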