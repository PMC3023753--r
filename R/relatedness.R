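#' Marker-based kinship matrix
#'
#' Moment estimator of pairwise kinship from dominant fragment
#' presence/absence calls, in the Loiselle form: with `p_m` the
#' population presence frequency of fragment `m`, the coefficient for
#' clones i, j is `sum_m (x_im - p_m)(x_jm - p_m) / sum_m p_m (1 - p_m)`
#' over the fragments non-missing in both clones (pairwise deletion).
#' Negative off-diagonals are truncated at 0 (unrelated), the diagonal
#' is set to the maximal self-similarity 1 (dominant scoring hides
#' inbreeding), and `2K` is bent to positive semi-definiteness by the
#' smallest ridge `eps` in `{0} U {1e-8 * 2^t}` when needed.
#'
#' @param markers Marker tibble or matrix (0/1/NA).
#' @param estimator `"loiselle"` (default) or `"similarity"` (scaled
#'   proportion of shared fragment states).
#' @param clip_negative Truncate negative off-diagonals at 0.
#' @param self_kinship Value placed on the diagonal.
#' @return A `kinship_matrix`: symmetric clones x clones matrix with
#'   attributes `bent` (logical) and `epsilon` (ridge added to 2K).
#' @export
kinship_matrix <- function(markers,
                           estimator = c("loiselle", "similarity"),
                           clip_negative = TRUE, self_kinship = 1) {
  estimator <- match.arg(estimator)
  x <- as_marker_matrix(markers)
  if (nrow(x) < 2L) {
    abort("need at least 2 clones.", class = "bruisemap_input_error")
  }
  pbar <- colMeans(x, na.rm = TRUE)
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1
  if (sum(poly) < 2L) {
    abort("fewer than 2 polymorphic fragments: kinship denominator degenerate.",
          class = "bruisemap_degenerate_error")
  }
  x <- x[, poly, drop = FALSE]
  pbar <- pbar[poly]

  obs <- !is.na(x)
  if (estimator == "loiselle") {
    z <- sweep(x, 2L, pbar)
    z[!obs] <- 0
    num <- tcrossprod(z)
    w <- pbar * (1 - pbar)
    den <- (obs * matrix(w, nrow(obs), ncol(obs), byrow = TRUE)) %*% t(obs)
    k <- num / den
  } else {
    xs <- x
    xs[!obs] <- 0
    agree <- tcrossprod(xs) + tcrossprod((1 - xs) * obs)
    nshared <- tcrossprod(obs * 1)
    sim <- agree / nshared
    # scale so expected value for unrelated clones is ~0
    k <- 2 * sim - 1
  }
  if (clip_negative) {
    k[k < 0] <- 0
  }
  diag(k) <- self_kinship
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(x), rownames(x))

  min_eig <- min(eigen(2 * k, symmetric = TRUE, only.values = TRUE)$values)
  eps <- 0
  if (min_eig < 0) {
    t_pow <- 0
    repeat {
      eps <- 1e-8 * 2^t_pow
      if (eps / 2 + min_eig / 2 >= 0 || eps >= -min_eig) break
      t_pow <- t_pow + 1
    }
  }
  structure(k, class = c("kinship_matrix", "matrix"),
            bent = eps > 0, epsilon = eps, estimator = estimator)
}

#' Bent genetic covariance 2K
#'
#' The kinship-structured covariance `2K + eps * I` used by the PK
#' model, with the ridge recorded on the kinship object applied.
#'
#' @param k A [kinship_matrix()].
#' @return Dense symmetric positive semi-definite matrix.
#' @export
genetic_covariance <- function(k) {
  eps <- attr(k, "epsilon") %||% 0
  m <- 2 * unclass(k)
  if (eps > 0) m <- m + diag(eps, nrow(m))
  m
}

#' Population structure by principal coordinates
#'
#' Classical principal-coordinate analysis of the fragment
#' presence/absence matrix (equivalently, principal components of the
#' fragment-mean-imputed, column-centered 0/1 matrix). The number of
#' retained axes `q` is the smallest integer whose cumulative explained
#' variance reaches `target_variance` (the "about 25%" rule).
#'
#' @param markers Marker tibble or matrix.
#' @param target_variance Cumulative explained-variance target in
#'   (0, 1].
#' @return A `pcoa_structure` object: list with `scores` (tibble:
#'   `clone`, `PCo1` ... `PCoq`), `q`, `explained` (per-axis variance
#'   fractions, all axes), `target_variance`.
#' @export
pcoa_structure <- function(markers, target_variance = 0.25) {
  if (!is.numeric(target_variance) || length(target_variance) != 1L ||
      !is.finite(target_variance) || target_variance <= 0 ||
      target_variance > 1) {
    abort("`target_variance` must lie in (0, 1].",
          class = "bruisemap_invalid_config")
  }
  x <- as_marker_matrix(markers)
  if (nrow(x) < 3L) {
    abort("need at least 3 clones.", class = "bruisemap_input_error")
  }
  xm <- apply(x, 2L, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  keep <- apply(xm, 2L, function(col) stats::var(col) > 0)
  xm <- xm[, keep, drop = FALSE]
  pc <- prcomp(xm, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  q <- which(cumsum(frac) >= target_variance)[1]
  scores <- pc$x[, seq_len(q), drop = FALSE]
  colnames(scores) <- paste0("PCo", seq_len(q))
  structure(
    list(
      scores = bind_cols(tibble(clone = rownames(x)),
                         as_tibble(scores, .name_repair = "minimal")),
      q = q,
      explained = frac,
      target_variance = target_variance
    ),
    class = "pcoa_structure")
}

#' @export
print.pcoa_structure <- function(x, ...) {
  cat(sprintf(
    "Principal-coordinate structure: %d clones, q = %d axes (%.1f%% variance, target %.0f%%)\n",
    nrow(x$scores), x$q, 100 * sum(x$explained[seq_len(x$q)]),
    100 * x$target_variance))
  invisible(x)
}

# Structure scores as a plain matrix aligned to given clone ids.
structure_matrix <- function(p, clones) {
  if (is.null(p)) {
    return(matrix(numeric(0), nrow = length(clones), ncol = 0L))
  }
  if (inherits(p, "pcoa_structure")) {
    s <- as.matrix(p$scores[-1])
    rownames(s) <- p$scores$clone
  } else if (is.matrix(p)) {
    s <- p
  } else {
    s <- as.matrix(as_tibble(p)[-1])
    rownames(s) <- as_tibble(p)$clone
  }
  idx <- match(clones, rownames(s))
  if (anyNA(idx)) {
    abort("structure matrix lacks some clones.",
          class = "bruisemap_input_error")
  }
  s[idx, , drop = FALSE]
}
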