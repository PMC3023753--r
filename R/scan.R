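#' Single-marker PK association scan
#'
#' Fits the PK mixed model once per polymorphic fragment, testing the
#' fragment as the last fixed term. Clones with a missing call for a
#' fragment are excluded for that test only (kinship, structure and
#' residual weights are subset accordingly). Fragments with fewer than
#' `min_count` carriers or non-carriers are skipped with a logged
#' reason. Variance components are re-estimated for every marker by
#' default; `reuse_vc = TRUE` fixes the variance ratio at the null-model
#' REML estimate (fast mode).
#'
#' No multiplicity correction is applied to `p_value` (raw thresholds
#' of 0.01 / 0.001 are the reporting convention); a Benjamini-Hochberg
#' `p_adj` column is emitted additionally but never gates output.
#'
#' @param means An [adjusted_entry_means()] result.
#' @param kinship A [kinship_matrix()].
#' @param structure A [pcoa_structure()] (or scores matrix), or `NULL`.
#' @param markers Marker tibble or matrix.
#' @param p_threshold Keep only records with `p_value` below this
#'   threshold (`1` keeps everything).
#' @param min_count Minimum carriers and non-carriers for a fragment to
#'   be testable.
#' @param metadata Optional fragment metadata tibble (`fragment`,
#'   `locus`, `chromosome`) merged into the output.
#' @param reuse_vc Reuse the null-model variance ratio for every marker
#'   instead of refitting (EMMAX-style fast mode).
#' @param test `"wald"` (default): Wald t on residual degrees of
#'   freedom; `"lr"`: likelihood-ratio test of the marker term on one
#'   chi-square degree of freedom, with both models maximized under
#'   the full (ML) likelihood.
#' @return A tibble of association records sorted by p-value: `trait`,
#'   `fragment`, `effect` (presence minus absence, trait units),
#'   `direction`, `se`, `statistic`, `p_value`, `p_adj`,
#'   `effect_popdev` (deviation of carriers from the population mean),
#'   `frequency` (percent carriers among non-missing), `n_used`; with
#'   attribute `skipped` (tibble of fragment, reason).
#' @export
scan_markers <- function(means, kinship, structure = NULL, markers,
                         p_threshold = 1, min_count = 5,
                         metadata = NULL, reuse_vc = FALSE,
                         test = c("wald", "lr")) {
  test <- match.arg(test)
  x <- as_marker_matrix(markers)
  m <- as_tibble(means)
  if ("estimable" %in% names(m)) m <- filter(m, .data$estimable)
  m <- filter(m, is.finite(.data$estimate))
  clones <- intersect(m$clone, rownames(x))
  if (length(clones) < length(m$clone)) {
    inform(sprintf("%d clone(s) with entry means but no marker data dropped.",
                   length(m$clone) - length(clones)))
  }
  m <- m[match(clones, m$clone), ]
  trait <- attr(means, "trait") %||% m$trait[1] %||% NA_character_
  y <- setNames(m$estimate, clones)
  r <- setNames(m$se^2, clones)
  if (any(!is.finite(r) | r <= 0)) {
    abort("residual weight matrix has a non-positive diagonal entry.",
          class = "bruisemap_input_error")
  }
  k2 <- align_kinship(kinship, clones)
  p_all <- structure_matrix(structure, clones)
  x <- x[clones, , drop = FALSE]

  ctx_full <- pk_context(y, r, k2, p_all)
  lambda_null <- NULL
  if (reuse_vc) {
    null_fit <- fit_pk_aligned(y, r, k2, p_all, xm = NULL,
                               ctx = ctx_full)
    lambda_null <- null_fit$lambda
  }
  ml_null_full <- if (test == "lr") pk_ml_max(ctx_full, ctx_full$xbase)

  skipped <- list()
  records <- list()
  for (fr in colnames(x)) {
    calls <- x[, fr]
    ok <- !is.na(calls)
    n_carrier <- sum(calls[ok] == 1L)
    n_non <- sum(calls[ok] == 0L)
    if (n_carrier < min_count || n_non < min_count) {
      reason <- if (n_carrier == 0L || n_non == 0L) "monomorphic" else
        sprintf("fewer than %d carriers or non-carriers", min_count)
      skipped[[fr]] <- tibble(fragment = fr, reason = reason)
      next
    }
    if (all(ok)) {
      fit <- try(fit_pk_aligned(y, r, k2, p_all,
                                xm = matrix(as.numeric(calls),
                                            dimnames = list(NULL, fr)),
                                lambda_fixed = lambda_null,
                                ctx = ctx_full),
                 silent = TRUE)
    } else {
      sub <- clones[ok]
      fit <- try(fit_pk_aligned(
        y[sub], r[sub], k2[ok, ok, drop = FALSE],
        p_all[ok, , drop = FALSE],
        xm = matrix(as.numeric(calls[ok]),
                    dimnames = list(NULL, fr)),
        lambda_fixed = lambda_null), silent = TRUE)
    }
    if (inherits(fit, "try-error")) {
      skipped[[fr]] <- tibble(fragment = fr,
                              reason = conditionMessage(
                                attr(fit, "condition")))
      next
    }
    i <- nrow(fit$coef)
    eff <- fit$coef$estimate[i]
    freq <- 100 * n_carrier / (n_carrier + n_non)
    if (test == "lr") {
      ctx_m <- fit$ctx
      xb <- ctx_m$xbase
      xa <- cbind(xb, ctx_m$ut_r %*% matrix(as.numeric(calls[ok])))
      ml0 <- if (all(ok)) ml_null_full else pk_ml_max(ctx_m, xb)
      ml1 <- pk_ml_max(ctx_m, xa)
      stat_v <- max(0, 2 * (ml1 - ml0))
      p_v <- pchisq(stat_v, df = 1, lower.tail = FALSE)
    } else {
      stat_v <- fit$coef$statistic[i]
      p_v <- fit$wald_p
    }
    records[[fr]] <- tibble(
      trait = trait, fragment = fr, effect = eff,
      direction = ifelse(eff >= 0, "increase", "decrease"),
      se = fit$coef$se[i], statistic = stat_v,
      p_value = p_v,
      effect_popdev = eff * (1 - freq / 100),
      frequency = freq, n_used = fit$n_used
    )
  }
  skipped <- if (length(skipped)) purrr::list_rbind(skipped) else
    tibble(fragment = character(), reason = character())
  if (!length(records)) {
    warn("no testable fragments; returning an empty association table.")
    out <- tibble(trait = character(), fragment = character(),
                  effect = numeric(), direction = character(),
                  se = numeric(), statistic = numeric(),
                  p_value = numeric(), p_adj = numeric(),
                  effect_popdev = numeric(), frequency = numeric(),
                  n_used = integer())
  } else {
    out <- purrr::list_rbind(records) |>
      mutate(p_adj = p.adjust(.data$p_value, method = "BH")) |>
      arrange(.data$p_value) |>
      filter(.data$p_value < !!p_threshold | !!p_threshold >= 1)
  }
  if (!is.null(metadata)) {
    out <- left_join(out, as_tibble(metadata), by = "fragment")
  }
  structure(out, skipped = skipped, class = c("pk_scan", class(out)))
}

#' Multi-locus forward selection under the PK model
#'
#' Iteratively builds a multi-marker model: at each step every
#' not-yet-selected testable fragment is fitted as the last fixed term
#' of the PK model containing all previously selected fragments as
#' fixed covariates (variance components re-estimated each fit); the
#' fragment with the smallest Wald p-value enters if it beats
#' `p_enter`, and the procedure stops when none qualifies. Ties on the
#' minimal p-value break by larger absolute effect, then by fragment
#' name. The explained genetic variance is the percent reduction of the
#' REML genetic variance component between the null model and the model
#' with all selected fragments, floored at 0.
#'
#' @inheritParams scan_markers
#' @param p_enter P-to-enter criterion.
#' @param max_steps Safety cap on the number of entered fragments.
#' @return A `forward_selection` object: tibble `steps` (fragment,
#'   p_at_entry, effect, se at entry), `explained_genetic_variance`
#'   (percent), `base_sigma2_gtilde`, `final_sigma2_gtilde`, `skipped`.
#' @export
forward_select <- function(means, kinship, structure = NULL, markers,
                           p_enter = 0.001, min_count = 5,
                           max_steps = Inf) {
  x <- as_marker_matrix(markers)
  m <- as_tibble(means)
  if ("estimable" %in% names(m)) m <- filter(m, .data$estimable)
  m <- filter(m, is.finite(.data$estimate))
  clones <- intersect(m$clone, rownames(x))
  m <- m[match(clones, m$clone), ]
  trait <- attr(means, "trait") %||% m$trait[1] %||% NA_character_
  y <- setNames(m$estimate, clones)
  r <- setNames(m$se^2, clones)
  k2 <- align_kinship(kinship, clones)
  p_all <- structure_matrix(structure, clones)
  x <- x[clones, , drop = FALSE]

  # candidate pool: complete-call polymorphic fragments with enough
  # carriers; fragments with missing calls are imputed at the fragment
  # mean so the joint multi-marker design shares one clone set
  pool <- character(0)
  skipped <- list()
  xnum <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (fr in colnames(x)) {
    calls <- x[, fr]
    ok <- !is.na(calls)
    n_carrier <- sum(calls[ok] == 1L)
    n_non <- sum(calls[ok] == 0L)
    if (n_carrier < min_count || n_non < min_count) {
      skipped[[fr]] <- tibble(
        fragment = fr,
        reason = if (n_carrier == 0L || n_non == 0L) "monomorphic" else
          sprintf("fewer than %d carriers or non-carriers", min_count))
      next
    }
    v <- as.numeric(calls)
    v[!ok] <- mean(v, na.rm = TRUE)
    xnum[, fr] <- v
    pool <- c(pool, fr)
  }

  base_fit <- fit_pk_aligned(y, r, k2, p_all)
  base_s2g <- base_fit$sigma2_gtilde

  selected <- character(0)
  steps <- list()
  while (length(pool) && length(selected) < max_steps) {
    cand <- purrr::map(pool, function(fr) {
      xm <- xnum[, c(selected, fr), drop = FALSE]
      fit <- try(fit_pk_aligned(y, r, k2, p_all, xm = xm),
                 silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      i <- nrow(fit$coef)
      tibble(fragment = fr, p_value = fit$wald_p,
             effect = fit$coef$estimate[i], se = fit$coef$se[i])
    })
    failed <- pool[purrr::map_lgl(cand, is.null)]
    for (fr in failed) {
      skipped[[fr]] <- tibble(fragment = fr,
                              reason = "collinear with selected set")
    }
    cand <- purrr::list_rbind(cand)
    pool <- setdiff(pool, failed)
    if (!nrow(cand)) break
    cand <- cand |>
      arrange(.data$p_value, dplyr::desc(abs(.data$effect)),
              .data$fragment)
    best <- cand[1, ]
    if (!is.finite(best$p_value) || best$p_value >= p_enter) break
    selected <- c(selected, best$fragment)
    pool <- setdiff(pool, best$fragment)
    steps[[length(steps) + 1L]] <- mutate(best,
                                          step = length(selected))
  }

  final_s2g <- if (length(selected)) {
    fit_pk_aligned(y, r, k2, p_all,
                   xm = xnum[, selected, drop = FALSE])$sigma2_gtilde
  } else {
    base_s2g
  }
  ev <- if (base_s2g > 0) {
    max(0, 100 * (base_s2g - final_s2g) / base_s2g)
  } else {
    0
  }
  structure(
    list(
      trait = trait,
      steps = if (length(steps)) purrr::list_rbind(steps) else
        tibble(fragment = character(), p_value = numeric(),
               effect = numeric(), se = numeric(), step = integer()),
      explained_genetic_variance = ev,
      base_sigma2_gtilde = base_s2g,
      final_sigma2_gtilde = final_s2g,
      skipped = if (length(skipped)) purrr::list_rbind(skipped) else
        tibble(fragment = character(), reason = character())
    ),
    class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("Forward selection (%s): %d fragment(s), explained genetic variance %.1f%%\n",
              x$trait %||% "?", nrow(x$steps),
              x$explained_genetic_variance))
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}
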