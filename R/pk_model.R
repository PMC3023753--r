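# PK (Q+K) mixed model: y_i = mu + sum_u P_iu v_u + x_i a + g_i + e_i
# with Var(g) = 2K sigma2_gtilde and Var(e) = R sigma2_r, R diagonal
# (squared SEs of the adjusted entry means). REML by whitening with
# R^{-1/2}, a one-time spectral decomposition of R^{-1/2} 2K R^{-1/2},
# and bracketed one-dimensional optimization of the restricted
# likelihood profiled over the variance ratio lambda = s2_g / s2_r.

pk_context <- function(y, r, k2, p_mat) {
  n <- length(y)
  rsq <- sqrt(r)
  b <- k2 / tcrossprod(rsq)
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ut <- t(eg$vectors)
  ut_r <- sweep(ut, 2L, rsq, "/")       # U' R^{-1/2}, applied to data
  list(
    n = n,
    d = d,
    ut_r = ut_r,
    ystar = as.vector(ut_r %*% y),
    xbase = ut_r %*% cbind(`(Intercept)` = 1, p_mat),
    # Jacobian of the whitening, so the reported restricted likelihood
    # is on the original data scale (comparable to a dense-V fit)
    log_jac = -0.5 * sum(log(r))
  )
}

# Full (ML) log-likelihood profiled over sigma2_r at fixed lambda;
# used by the likelihood-ratio variant of the marker test.
pk_ml_profile <- function(ctx, xstar, lambda) {
  v <- lambda * ctx$d + 1
  sw <- 1 / sqrt(v)
  xw <- xstar * sw
  yw <- ctx$ystar * sw
  n <- ctx$n
  qr_x <- qr(xw)
  if (qr_x$rank < ncol(xstar)) return(-1e300)
  beta <- qr.coef(qr_x, yw)
  rss <- sum((yw - xw %*% beta)^2)
  s2r <- rss / n
  if (s2r <= 0 || !is.finite(s2r)) return(-1e300)
  ll <- -0.5 * (n * log(s2r) + sum(log(v)) + n * (1 + log(2 * pi))) +
    ctx$log_jac
  if (!is.finite(ll)) -1e300 else ll
}

pk_ml_max <- function(ctx, xstar) {
  grid <- 10^seq(-8, 8, by = 0.5)
  glls <- vapply(grid, function(l) pk_ml_profile(ctx, xstar, l),
                 numeric(1L))
  i0 <- which.max(glls)
  lo <- log(grid[max(1L, i0 - 1L)])
  hi <- log(grid[min(length(grid), i0 + 1L)])
  opt <- optimize(function(ll) pk_ml_profile(ctx, xstar, exp(ll)),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
  max(opt$objective, pk_ml_profile(ctx, xstar, 0))
}

# Restricted log-likelihood profiled over sigma2_r at fixed ratio
# lambda, plus the GLS pieces needed at the optimum.
pk_profile <- function(ctx, xstar, lambda, details = FALSE) {
  v <- lambda * ctx$d + 1
  sw <- 1 / sqrt(v)
  xw <- xstar * sw
  yw <- ctx$ystar * sw
  n <- ctx$n
  p <- ncol(xstar)
  qr_x <- qr(xw)
  if (qr_x$rank < p) {
    if (!details) return(-1e300)
    abort("rank-deficient design inside pk_profile.",
          class = "bruisemap_rank_error")
  }
  beta <- qr.coef(qr_x, yw)
  rss <- sum((yw - xw %*% beta)^2)
  df <- n - p
  s2r <- rss / df
  if (s2r <= 0 || !is.finite(s2r)) return(if (details) NULL else -1e300)
  rmat <- qr.R(qr_x)
  logdet_xwx <- 2 * sum(log(abs(diag(rmat))))
  ll <- -0.5 * (df * log(s2r) + sum(log(v)) + logdet_xwx +
                  df * (1 + log(2 * pi))) + ctx$log_jac
  if (!is.finite(ll)) {
    if (!details) return(-1e300)
  }
  if (!details) return(ll)
  xtx_inv <- chol2inv(rmat)
  se <- sqrt(pmax(diag(xtx_inv), 0) * s2r)
  list(loglik = ll, beta = as.vector(beta), se = se, s2r = s2r,
       lambda = lambda, df = df, rank = qr_x$rank)
}

#' Fit the PK (Q+K) mixed model to adjusted entry means
#'
#' Regresses adjusted entry means on an intercept, the
#' population-structure axes and (optionally) one or more marker
#' fragments, with a kinship-structured polygenic effect
#' (`Var(g) = 2 K sigma2_gtilde`) and heteroscedastic residuals
#' (`Var(e) = R sigma2_r`, `R` the diagonal of squared entry-mean
#' standard errors). The two variance components are estimated by REML
#' via a one-time simultaneous diagonalization and a profiled
#' one-dimensional search over the variance ratio (the boundary
#' `sigma2_gtilde = 0` is checked explicitly); fixed effects are GLS at
#' the optimum. The last marker column is tested with a Wald t
#' statistic on `n - rank(design)` degrees of freedom.
#'
#' @param means An [adjusted_entry_means()] result (or tibble with
#'   `clone`, `estimate`, `se`).
#' @param kinship A [kinship_matrix()] (or bare symmetric matrix with
#'   clone dimnames).
#' @param structure A [pcoa_structure()], a scores matrix/tibble, or
#'   `NULL` for no structure correction.
#' @param marker_values Named vector, single-column matrix, or multi-
#'   column matrix of fragment codes (0/1) per clone; the last column
#'   is the tested term. `NULL` fits the null polygenic model.
#' @param r_weights Optional named vector of residual diagonal entries;
#'   defaults to the squared standard errors in `means`.
#' @param lambda_fixed Fix the variance ratio instead of estimating it
#'   (used by the fast scan mode).
#' @return A `pk_fit` object: `sigma2_gtilde`, `sigma2_r`, `lambda`,
#'   `loglik` (restricted), `coef` tibble (term, estimate, se,
#'   statistic, p_value), `wald_p` for the tested term, `df`, `n_used`.
#' @export
fit_pk <- function(means, kinship, structure = NULL,
                   marker_values = NULL, r_weights = NULL,
                   lambda_fixed = NULL) {
  m <- as_tibble(means)
  if ("estimable" %in% names(m)) m <- filter(m, .data$estimable)
  m <- filter(m, is.finite(.data$estimate))
  clones <- m$clone
  y <- setNames(m$estimate, clones)
  r <- r_weights %||% setNames(m$se^2, clones)
  r <- r[clones]
  if (any(!is.finite(r) | r <= 0)) {
    abort("residual weight matrix has a non-positive diagonal entry.",
          class = "bruisemap_input_error")
  }
  kk <- align_kinship(kinship, clones)
  p_mat <- structure_matrix(structure, clones)

  xm <- NULL
  if (!is.null(marker_values)) {
    xm <- as.matrix(marker_values)
    if (is.null(rownames(xm)) && nrow(xm) == length(clones)) {
      rownames(xm) <- clones
    }
    idx <- match(clones, rownames(xm))
    if (anyNA(idx)) {
      abort("marker values lack some clones in `means`.",
            class = "bruisemap_input_error")
    }
    xm <- xm[idx, , drop = FALSE]
    if (anyNA(xm)) {
      abort("marker values contain missing calls; subset clones first.",
            class = "bruisemap_input_error")
    }
    if (is.null(colnames(xm))) {
      colnames(xm) <- paste0("marker", seq_len(ncol(xm)))
    }
  }
  fit_pk_aligned(y, r, kk, p_mat, xm, lambda_fixed)
}

align_kinship <- function(kinship, clones) {
  k2 <- genetic_covariance(
    if (inherits(kinship, "kinship_matrix")) kinship else
      structure(kinship, class = c("kinship_matrix", "matrix")))
  if (!is.null(rownames(k2))) {
    idx <- match(clones, rownames(k2))
    if (anyNA(idx)) {
      abort("kinship matrix lacks some clones in `means`.",
            class = "bruisemap_input_error")
    }
    k2 <- k2[idx, idx, drop = FALSE]
  } else if (nrow(k2) != length(clones)) {
    abort("kinship dimension does not match the clone set.",
          class = "bruisemap_input_error")
  }
  k2
}

fit_pk_aligned <- function(y, r, k2, p_mat, xm = NULL,
                           lambda_fixed = NULL, ctx = NULL) {
  ctx <- ctx %||% pk_context(y, r, k2, p_mat)
  xstar <- ctx$xbase
  if (!is.null(xm)) {
    xstar <- cbind(xstar, ctx$ut_r %*% xm)
    colnames(xstar) <- c(colnames(ctx$xbase), colnames(xm))
  }
  check_design_rank(xstar)

  if (is.null(lambda_fixed)) {
    # the profiled restricted likelihood in the ratio can be multimodal:
    # coarse log-spaced scan, then local refinement around the best
    # coarse point, with the boundary (no genetic variance) checked
    # explicitly
    grid <- 10^seq(-8, 8, by = 0.5)
    glls <- vapply(grid, function(l) pk_profile(ctx, xstar, l),
                   numeric(1L))
    i0 <- which.max(glls)
    lo <- log(grid[max(1L, i0 - 1L)])
    hi <- log(grid[min(length(grid), i0 + 1L)])
    opt <- optimize(function(ll) pk_profile(ctx, xstar, exp(ll)),
                    interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
    cand <- c(0, exp(opt$maximum))
    lls <- vapply(cand, function(l) pk_profile(ctx, xstar, l),
                  numeric(1L))
    lambda <- cand[which.max(lls)]
  } else {
    lambda <- lambda_fixed
  }
  det_fit <- pk_profile(ctx, xstar, lambda, details = TRUE)
  if (is.null(det_fit)) {
    abort("PK REML failed: degenerate residual variance.",
          class = "bruisemap_numerical_error")
  }
  terms <- colnames(xstar)
  stat <- det_fit$beta / det_fit$se
  pv <- 2 * pt(-abs(stat), det_fit$df)
  coef_tbl <- tibble(term = terms, estimate = det_fit$beta,
                     se = det_fit$se, statistic = stat, p_value = pv)
  tested <- if (!is.null(xm)) terms[length(terms)] else NA_character_
  structure(
    list(
      sigma2_gtilde = lambda * det_fit$s2r,
      sigma2_r = det_fit$s2r,
      lambda = lambda,
      loglik = det_fit$loglik,
      coef = coef_tbl,
      tested_term = tested,
      wald_p = if (!is.null(xm)) pv[length(pv)] else NA_real_,
      df = det_fit$df,
      n_used = ctx$n,
      ctx = ctx
    ),
    class = "pk_fit")
}

check_design_rank <- function(xstar) {
  qr_x <- qr(xstar, LAPACK = FALSE)
  if (qr_x$rank < ncol(xstar)) {
    bad <- colnames(xstar)[qr_x$pivot[(qr_x$rank + 1L):ncol(xstar)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "bruisemap_rank_error")
  }
  invisible(TRUE)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf(
    "PK mixed-model fit: n = %d, sigma2_gtilde = %.4g, sigma2_r = %.4g, REML logLik = %.4f\n",
    x$n_used, x$sigma2_gtilde, x$sigma2_r, x$loglik))
  if (!is.na(x$tested_term)) {
    i <- nrow(x$coef)
    cat(sprintf("  tested term %s: effect = %.4g (se %.3g), p = %.3g\n",
                x$tested_term, x$coef$estimate[i], x$coef$se[i],
                x$wald_p))
  }
  invisible(x)
}
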