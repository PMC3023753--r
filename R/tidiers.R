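# broom-style methods for the package's fitted objects.

#' @exportS3Method generics::tidy
tidy.plot_model_fit <- function(x, ...) {
  tibble(component = names(x$vc), variance = unname(x$vc))
}

#' @exportS3Method generics::glance
glance.plot_model_fit <- function(x, ...) {
  tibble(trait = x$trait, reml_loglik = x$loglik, n_obs = x$n_obs,
         n_clones = dplyr::n_distinct(x$data$clone),
         n_environments = dplyr::n_distinct(x$data$environment))
}

#' @export
print.plot_model_fit <- function(x, ...) {
  cat(sprintf("Plot-model REML fit for '%s' (%d obs): logLik = %.3f\n",
              x$trait, x$n_obs, x$loglik))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pk_fit <- function(x, ...) {
  x$coef
}

#' @exportS3Method generics::glance
glance.pk_fit <- function(x, ...) {
  tibble(sigma2_gtilde = x$sigma2_gtilde, sigma2_r = x$sigma2_r,
         lambda = x$lambda, reml_loglik = x$loglik, df = x$df,
         n_used = x$n_used)
}

#' @exportS3Method generics::tidy
tidy.pcoa_structure <- function(x, ...) {
  tibble(axis = seq_along(x$explained),
         explained_variance = x$explained,
         cumulative = cumsum(x$explained),
         retained = seq_along(x$explained) <= x$q)
}

#' @exportS3Method generics::augment
augment.pcoa_structure <- function(x, ...) {
  x$scores
}

#' @exportS3Method generics::tidy
tidy.kinship_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame.table(m, responseName = "kinship",
                                stringsAsFactors = FALSE)) |>
    rename(clone_i = "Var1", clone_j = "Var2")
}

#' @exportS3Method generics::glance
glance.kinship_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(n_clones = nrow(m),
         mean_offdiag = mean(m[lower.tri(m)]),
         bent = isTRUE(attr(x, "bent")),
         epsilon = attr(x, "epsilon") %||% 0,
         estimator = attr(x, "estimator") %||% NA_character_)
}

#' @exportS3Method generics::tidy
tidy.forward_selection <- function(x, ...) {
  x$steps
}

#' @exportS3Method generics::glance
glance.forward_selection <- function(x, ...) {
  tibble(trait = x$trait, n_selected = nrow(x$steps),
         explained_genetic_variance = x$explained_genetic_variance,
         base_sigma2_gtilde = x$base_sigma2_gtilde,
         final_sigma2_gtilde = x$final_sigma2_gtilde)
}
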