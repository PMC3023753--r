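#' GLS-adjusted entry means with standard errors
#'
#' Stage-one BLUEs: with genotype treated as fixed and the non-genetic
#' effects (environment, G x E, replicate-within-environment, residual)
#' random at their estimated variance components, computes for every
#' clone the generalized-least-squares estimate `M_i = mu_hat + g_hat_i`
#' of its trait value across environments, its standard error from the
#' fixed-effect covariance `(X' V^-1 X)^-1`, and the mean variance of a
#' difference between two adjusted entry means (`wbar`), the quantity
#' entering entry-mean heritability. Squared standard errors form the
#' diagonal of the residual weight matrix of the stage-two association
#' scan.
#'
#' Computation uses Henderson's mixed-model equations on sparse
#' incidence matrices; the top-left block of the inverted coefficient
#' matrix is the exact GLS covariance of the entry means.
#'
#' @param plots Plot table (long format).
#' @param trait Trait to analyse.
#' @param vc A [fit_plot_model()] result, or any list with a named `vc`
#'   vector of the five components.
#' @return A tibble of class `entry_means` with columns `clone`,
#'   `trait`, `estimate`, `se`, `n_obs`, `estimable`; attributes `wbar`
#'   (mean variance of a difference) and `vcov` (clones x clones GLS
#'   covariance).
#' @export
adjusted_entry_means <- function(plots, trait, vc) {
  plots <- validate_plot_table(plots)
  all_clones <- unique(filter(plots, .data$trait == !!trait)$clone)
  d <- filter(plots, .data$trait == !!trait, !is.na(.data$value))
  if (nrow(d) == 0L) {
    abort(sprintf("no observations for trait '%s'.", trait),
          class = "bruisemap_insufficient_data")
  }
  comp <- vc$vc
  stopifnot(all(c("sigma2_env", "sigma2_gxe", "sigma2_rep",
                  "sigma2_e") %in% names(comp)))

  obs_clones <- sort(unique(d$clone))
  clone_f <- factor(d$clone, levels = obs_clones)
  x <- Matrix::sparse.model.matrix(~ 0 + clone_f)
  colnames(x) <- obs_clones

  # residual variance floored to keep the equations well-posed when a
  # degenerate fit returned exactly zero
  s2e <- max(comp[["sigma2_e"]], 1e-8 * max(var(d$value), 1e-8), 1e-12)

  zs <- list()
  gvar <- numeric(0)
  add_term <- function(zs, gvar, fac, s2) {
    if (s2 > 0) {
      z <- Matrix::sparse.model.matrix(~ 0 + factor(fac))
      zs[[length(zs) + 1L]] <- z
      gvar <- c(gvar, rep(s2, ncol(z)))
    }
    list(zs = zs, gvar = gvar)
  }
  tmp <- add_term(zs, gvar, d$environment, comp[["sigma2_env"]])
  tmp <- add_term(tmp$zs, tmp$gvar,
                  paste(d$clone, d$environment, sep = ":"),
                  comp[["sigma2_gxe"]])
  tmp <- add_term(tmp$zs, tmp$gvar,
                  paste(d$environment, d$replicate, sep = ":"),
                  comp[["sigma2_rep"]])
  zs <- tmp$zs; gvar <- tmp$gvar

  p <- ncol(x)
  if (length(zs)) {
    z <- do.call(cbind, zs)
    cmat <- rbind(
      cbind(Matrix::crossprod(x) / s2e, Matrix::crossprod(x, z) / s2e),
      cbind(Matrix::crossprod(z, x) / s2e,
            Matrix::crossprod(z) / s2e + Matrix::Diagonal(x = 1 / gvar))
    )
    rhs_dim <- p + ncol(z)
  } else {
    cmat <- Matrix::crossprod(x) / s2e
    rhs_dim <- p
  }
  rhs <- numeric(rhs_dim)
  rhs[seq_len(p)] <- as.vector(Matrix::crossprod(x, d$value)) / s2e
  if (length(zs)) {
    rhs[-seq_len(p)] <- as.vector(Matrix::crossprod(z, d$value)) / s2e
  }

  ch <- Matrix::Cholesky(Matrix::forceSymmetric(cmat), LDL = FALSE,
                         perm = TRUE)
  sol <- Matrix::solve(ch, rhs)
  beta <- as.vector(sol)[seq_len(p)]

  # GLS covariance of the entry means: top-left block of C^-1
  e_blk <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                                dims = c(rhs_dim, p))
  cov_beta <- as.matrix(Matrix::solve(ch, e_blk))[seq_len(p), ,
                                                  drop = FALSE]
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  dimnames(cov_beta) <- list(obs_clones, obs_clones)
  se <- sqrt(pmax(diag(cov_beta), 0))

  tr <- sum(diag(cov_beta))
  s <- sum(cov_beta)
  wbar <- if (p > 1L) 2 * (p * tr - s) / (p * (p - 1)) else NA_real_

  n_obs <- as.vector(table(clone_f))
  out <- tibble(
    clone = obs_clones, trait = trait, estimate = unname(beta),
    se = unname(se), n_obs = n_obs, estimable = TRUE
  )
  dropped <- setdiff(all_clones, obs_clones)
  if (length(dropped)) {
    out <- bind_rows(out, tibble(
      clone = dropped, trait = trait, estimate = NA_real_,
      se = NA_real_, n_obs = 0L, estimable = FALSE))
    inform(sprintf("%d clone(s) without observations flagged inestimable.",
                   length(dropped)))
  }
  structure(out, wbar = wbar, trait = trait, vcov = cov_beta,
            class = c("entry_means", class(out)))
}

#' Residual weight matrix for the stage-two scan
#'
#' Diagonal matrix of squared standard errors of the adjusted entry
#' means, restricted to estimable clones.
#'
#' @param means An [adjusted_entry_means()] result.
#' @return Named vector of positive diagonal entries (one per clone).
#' @export
residual_weights <- function(means) {
  m <- filter(as_tibble(means), .data$estimable)
  r <- setNames(m$se^2, m$clone)
  if (any(!is.finite(r) | r <= 0)) {
    abort("non-positive squared standard error in residual weights.",
          class = "bruisemap_input_error")
  }
  r
}
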