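# Independent oracles and small fixture builders used across tests.
# Every oracle here deliberately avoids the code path it checks.

# Dense-V REML for the PK model: build V = 2K s2g + R s2r explicitly
# and maximize the generic restricted likelihood with a 2-d optimizer.
pk_dense_oracle <- function(y, x, k, r_diag) {
  f <- function(par) {
    v <- 2 * k * exp(par[1]) + diag(r_diag) * exp(par[2])
    -bruisemap:::reml_loglik_dense(y, x, v)
  }
  o <- stats::optim(c(0, 0), f, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 10000))
  list(loglik = -o$value, sigma2_gtilde = exp(o$par[1]),
       sigma2_r = exp(o$par[2]))
}

# Classical forward-stepwise OLS: add the regressor with the smallest
# partial-F/t p-value while it beats p_enter.
ols_forward_oracle <- function(y, xmat, covariates = NULL,
                               p_enter = 0.05) {
  selected <- character(0)
  pool <- colnames(xmat)
  repeat {
    ps <- vapply(pool, function(fr) {
      xx <- cbind(covariates, xmat[, c(selected, fr), drop = FALSE])
      fit <- stats::lm(y ~ xx)
      cf <- summary(fit)$coefficients
      rn <- rownames(cf)
      cf[rn[length(rn)], 4]
    }, numeric(1L))
    if (!length(ps) || min(ps, na.rm = TRUE) >= p_enter) break
    best <- names(which.min(ps))
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
  }
  selected
}

# Dense GLS of entry means: build the full V over plot observations
# and compute (X'V^-1 X)^-1 X'V^-1 y with genotype cell-means coding.
gls_entry_means_oracle <- function(plots, trait, vc) {
  d <- plots[plots$trait == trait & !is.na(plots$value), ]
  d <- d[order(d$clone), ]
  clones <- sort(unique(d$clone))
  x <- stats::model.matrix(~ 0 + factor(d$clone, levels = clones))
  n <- nrow(d)
  zz <- function(f) stats::model.matrix(~ 0 + factor(f))
  v <- diag(max(vc[["sigma2_e"]], 1e-10), n)
  if (vc[["sigma2_env"]] > 0) {
    z <- zz(d$environment); v <- v + vc[["sigma2_env"]] * tcrossprod(z)
  }
  if (vc[["sigma2_gxe"]] > 0) {
    z <- zz(paste(d$clone, d$environment))
    v <- v + vc[["sigma2_gxe"]] * tcrossprod(z)
  }
  if (vc[["sigma2_rep"]] > 0) {
    z <- zz(paste(d$environment, d$replicate))
    v <- v + vc[["sigma2_rep"]] * tcrossprod(z)
  }
  vi <- solve(v)
  cov_b <- solve(crossprod(x, vi %*% x))
  b <- cov_b %*% crossprod(x, vi %*% d$value)
  list(clone = clones, estimate = as.vector(b),
       se = unname(sqrt(diag(cov_b))), vcov = cov_b)
}

# Small balanced trial fixture.
small_trial <- function(seed = 3, n_clones = 15, n_markers = 40,
                        n_env = 4, n_rep = 2, ...) {
  cfg <- sim_config(n_clones = n_clones, n_markers = n_markers,
                    n_environments = n_env, n_replicates = n_rep,
                    missing_rate = 0, seed = seed, ...)
  sim <- simulate_markers(cfg)
  trial <- simulate_trial(sim, cfg)
  list(cfg = cfg, sim = sim, trial = trial)
}

# Entry-means tibble straight from a vector (stage-2-only fixtures).
means_fixture <- function(y, se = 1, trait = "BI") {
  cl <- names(y) %||% sprintf("c%03d", seq_along(y))
  structure(
    tibble::tibble(clone = cl, trait = trait, estimate = unname(y),
                   se = se, n_obs = 1L, estimable = TRUE),
    trait = trait,
    class = c("entry_means", class(tibble::tibble())))
}

`%||%` <- rlang::`%||%`

# PSD kinship fixture with unit diagonal.
random_kinship <- function(n, seed = 1) {
  withr::with_seed(seed, {
    k <- stats::cov2cor(crossprod(matrix(stats::rnorm(n * n), n)))
    cl <- sprintf("c%02d", seq_len(n))
    dimnames(k) <- list(cl, cl)
    structure(k, class = c("kinship_matrix", "matrix"), epsilon = 0,
              bent = FALSE)
  })
}

marker_tibble_for_test <- function(x) bruisemap:::marker_tibble(x)
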