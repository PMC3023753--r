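test_that("plot table validation catches schema problems", {
  good <- tibble::tibble(clone = "a", environment = "E1",
                         replicate = "R1", trait = "BI", value = 1)
  expect_s3_class(validate_plot_table(good), "tbl_df")
  expect_error(validate_plot_table(good[-1]),
               class = "bruisemap_schema_error")
  expect_error(validate_plot_table(rbind(good, good)),
               class = "bruisemap_schema_error")
})

test_that("constant response yields an exact all-zero variance fit", {
  plots <- tidyr::expand_grid(clone = sprintf("c%d", 1:6),
                              environment = c("E1", "E2"),
                              replicate = c("R1", "R2")) |>
    dplyr::mutate(trait = "BI", value = 12)
  fit <- fit_plot_model(plots, "BI")
  expect_equal(unname(fit$vc), rep(0, 5))
})

test_that("REML optimum meets or beats a five-dimensional grid", {
  fx <- small_trial(seed = 11, n_clones = 8, n_env = 2, n_rep = 2,
                    sigma2_g = 2, sigma2_env = 1, sigma2_gxe = 0.5,
                    sigma2_rep = 0.3, sigma2_e = 1, mu = 0)
  fit <- fit_plot_model(fx$trial$plots, "BI")
  d <- fit$data
  ll_opt <- bruisemap:::reml_loglik_plot(d, fit$vc)
  expect_equal(ll_opt, fit$loglik, tolerance = 1e-6)

  vy <- var(d$value)
  grid <- as.matrix(expand.grid(
    g = c(0, 0.2, 0.5, 1, 2) * vy, l = c(0, 0.2, 0.5, 1) * vy,
    gl = c(0, 0.2, 0.5, 1) * vy, r = c(0, 0.2, 0.5) * vy,
    e = c(0.05, 0.2, 0.5, 1, 2) * vy))
  lls <- apply(grid, 1, function(p) {
    p <- unname(p)
    bruisemap:::reml_loglik_plot(d, c(
      sigma2_g = p[1], sigma2_env = p[2], sigma2_gxe = p[3],
      sigma2_rep = p[4], sigma2_e = p[5]))
  })
  expect_gte(ll_opt, max(lls) - 1e-6)
})

test_that("REML estimates are invariant to relabeling environments and replicates", {
  fx <- small_trial(seed = 8)
  fit1 <- fit_plot_model(fx$trial$plots, "BI")
  relab <- fx$trial$plots |>
    dplyr::mutate(environment = paste0("env_", rev(environment)),
                  replicate = chartr("12", "21", replicate))
  fit2 <- fit_plot_model(relab, "BI")
  expect_equal(fit1$vc, fit2$vc, tolerance = 1e-5)
})

test_that("single-environment designs raise an identifiability error", {
  plots <- tidyr::expand_grid(clone = sprintf("c%d", 1:5),
                              environment = "E1",
                              replicate = c("R1", "R2")) |>
    dplyr::mutate(trait = "BI", value = rnorm(10))
  expect_error(fit_plot_model(plots, "BI"),
               class = "bruisemap_identifiability_error")
})

test_that("entry means equal arithmetic clone means on balanced data", {
  fx <- small_trial(seed = 3)
  vc <- fit_plot_model(fx$trial$plots, "BI")
  em <- adjusted_entry_means(fx$trial$plots, "BI", vc)
  raw <- fx$trial$plots |>
    dplyr::group_by(clone) |>
    dplyr::summarise(m = mean(value))
  expect_equal(em$estimate, raw$m[match(em$clone, raw$clone)],
               tolerance = 1e-8)
})

test_that("balanced wbar matches the closed-form entry-mean variance", {
  # shared environment and replicate effects cancel in differences, so
  # wbar = 2 sigma2_gxe / J + 2 sigma2_e / (J K)
  fx <- small_trial(seed = 3, n_env = 4, n_rep = 2)
  vc <- fit_plot_model(fx$trial$plots, "BI")
  em <- adjusted_entry_means(fx$trial$plots, "BI", vc)
  wbar_cf <- 2 * (vc$vc[["sigma2_gxe"]] / 4 + vc$vc[["sigma2_e"]] / 8)
  expect_equal(attr(em, "wbar"), wbar_cf, tolerance = 1e-8)
})

test_that("doubling the information shrinks entry-mean SEs by sqrt(2)", {
  # under a residual-only variance model duplicate plots with fresh
  # replicate labels double the information exactly
  fx <- small_trial(seed = 4, n_clones = 8, n_env = 2)
  vc0 <- list(vc = c(sigma2_g = 1, sigma2_env = 0, sigma2_gxe = 0,
                     sigma2_rep = 0, sigma2_e = 2), trait = "BI")
  em1 <- adjusted_entry_means(fx$trial$plots, "BI", vc0)
  dup <- dplyr::mutate(fx$trial$plots,
                       replicate = paste0(replicate, "_b"))
  em2 <- adjusted_entry_means(dplyr::bind_rows(fx$trial$plots, dup),
                              "BI", vc0)
  expect_equal(em1$se / em2$se[match(em1$clone, em2$clone)],
               rep(sqrt(2), nrow(em1)), tolerance = 1e-6)
})

test_that("unbalanced entry means match the dense GLS oracle", {
  fx <- small_trial(seed = 6, n_clones = 6, n_env = 3)
  plots <- fx$trial$plots
  # one clone observed only in environment E1
  lone <- plots$clone[1]
  plots <- plots[!(plots$clone == lone & plots$environment != "E1"), ]
  vc <- fit_plot_model(plots, "BI")
  em <- adjusted_entry_means(plots, "BI", vc)
  oracle <- gls_entry_means_oracle(plots, "BI", vc$vc)
  idx <- match(oracle$clone, em$clone)
  expect_equal(em$estimate[idx], oracle$estimate, tolerance = 1e-6)
  expect_equal(em$se[idx], oracle$se, tolerance = 1e-6)
  # the lone clone is shifted away from its raw mean by the
  # environment-1 adjustment
  raw <- mean(plots$value[plots$clone == lone])
  expect_gt(abs(em$estimate[em$clone == lone] - raw), 1e-6)
})

test_that("clones without observations are flagged, not dropped", {
  fx <- small_trial(seed = 6, n_clones = 6, n_env = 3)
  plots <- fx$trial$plots
  gone <- plots$clone[1]
  plots$value[plots$clone == gone] <- NA
  vc <- fit_plot_model(plots, "BI")
  expect_message(em <- adjusted_entry_means(plots, "BI", vc),
                 "inestimable")
  row <- em[em$clone == gone, ]
  expect_false(row$estimable)
  expect_true(is.na(row$estimate))
})

test_that("heritability follows the entry-mean formula", {
  vc <- list(vc = c(sigma2_g = 1, sigma2_env = 0, sigma2_gxe = 0,
                    sigma2_rep = 0, sigma2_e = 0), trait = "BI")
  fake_means <- structure(tibble::tibble(), wbar = 1)
  expect_equal(estimate_heritability(vc, fake_means)$h2, 1 / 1.5,
               tolerance = 1e-10)
  expect_equal(estimate_heritability(vc, fake_means,
                                     variant = "plabstat")$h2, 0.5)
  vc0 <- list(vc = c(sigma2_g = 0, sigma2_env = 0, sigma2_gxe = 0,
                     sigma2_rep = 0, sigma2_e = 0), trait = "BI")
  expect_equal(estimate_heritability(vc0, fake_means)$h2, 0)
  # wbar -> 0 drives h2 -> 1
  tiny <- structure(tibble::tibble(), wbar = 1e-12)
  expect_equal(estimate_heritability(vc, tiny)$h2, 1, tolerance = 1e-9)
  bad <- structure(tibble::tibble(), wbar = 0)
  expect_error(estimate_heritability(vc, bad),
               class = "bruisemap_degenerate_error")
})

test_that("SCB residuals are exactly orthogonal to specific gravity", {
  fx <- small_trial(seed = 13, n_clones = 20, n_env = 3)
  plots <- fx$trial$plots
  sg <- plots |>
    dplyr::mutate(trait = "SG",
                  value = 14 + 0.05 * value +
                    rnorm(nrow(plots), 0, 0.5))
  both <- dplyr::bind_rows(plots, sg)
  out <- compute_scb(both)
  wide <- out |>
    tidyr::pivot_wider(names_from = trait, values_from = value)
  expect_equal(mean(wide$SCB), 0, tolerance = 1e-10)
  expect_equal(abs(cor(wide$SCB, wide$SG)), 0, tolerance = 1e-10)
})

test_that("an exact linear BI-SG relation gives all-zero SCB", {
  plots <- tidyr::expand_grid(clone = sprintf("c%d", 1:6),
                              environment = c("E1", "E2"),
                              replicate = "R1")
  sg_val <- seq(12, 18, length.out = nrow(plots))
  both <- dplyr::bind_rows(
    dplyr::mutate(plots, trait = "SG", value = sg_val),
    dplyr::mutate(plots, trait = "BI", value = 2 * sg_val + 5))
  out <- compute_scb(both)
  expect_equal(out$value[out$trait == "SCB"],
               rep(0, nrow(plots)), tolerance = 1e-10)
})

test_that("SCB of BI independent of SG is essentially centered BI", {
  set.seed(77)
  n <- 1000
  plots <- tibble::tibble(clone = sprintf("c%04d", 1:n),
                          environment = "E1", replicate = "R1")
  bi <- runif(n, 0, 60)
  sg <- rnorm(n, 14, 1.5)
  both <- dplyr::bind_rows(
    dplyr::mutate(plots, trait = "BI", value = bi),
    dplyr::mutate(plots, trait = "SG", value = sg))
  scb <- compute_scb(both) |> dplyr::filter(trait == "SCB")
  expect_gt(cor(scb$value, bi - mean(bi)), 0.99)
})

test_that("constant SG makes the SCB regression degenerate", {
  plots <- tibble::tibble(clone = sprintf("c%d", 1:5),
                          environment = "E1", replicate = "R1")
  both <- dplyr::bind_rows(
    dplyr::mutate(plots, trait = "BI", value = rnorm(5)),
    dplyr::mutate(plots, trait = "SG", value = 14))
  expect_error(compute_scb(both),
               class = "bruisemap_degenerate_error")
})

test_that("trait correlations report rho, p and stars correctly", {
  y <- rnorm(30)
  means <- list(
    A = means_fixture(setNames(y, sprintf("c%03d", 1:30)), trait = "A"),
    B = means_fixture(setNames(-y, sprintf("c%03d", 1:30)), trait = "B"))
  ct <- trait_correlations(means)
  self <- ct[ct$trait_x == "A" & ct$trait_y == "A", ]
  expect_equal(self$r, 1)
  anti <- ct[ct$trait_x == "A" & ct$trait_y == "B", ]
  expect_equal(anti$r, -1, tolerance = 1e-12)
  expect_identical(anti$stars, "***")

  too_few <- list(A = means_fixture(c(a = 1, b = 2), trait = "A"),
                  B = means_fixture(c(a = 1, b = 2), trait = "B"))
  expect_error(trait_correlations(too_few),
               class = "bruisemap_insufficient_data")
})

test_that("SCB entry means are uncorrelated with SG entry means", {
  fx <- small_trial(seed = 19, n_clones = 120, n_env = 3)
  plots <- fx$trial$plots
  sg <- simulate_trial(fx$sim$markers,
                       sim_config(n_clones = 120, n_markers = 40,
                                  n_environments = 3, sigma2_g = 1,
                                  sigma2_env = 0.5, sigma2_gxe = 0.2,
                                  sigma2_rep = 0.1, sigma2_e = 0.3,
                                  mu = 14, trait = "SG",
                                  missing_rate = 0, seed = 20),
                       truth = fx$sim$truth)
  both <- dplyr::bind_rows(plots, sg$plots)
  both <- compute_scb(both)
  means <- lapply(c(SG = "SG", SCB = "SCB"), function(tr) {
    adjusted_entry_means(both, tr, fit_plot_model(both, tr))
  })
  ct <- trait_correlations(means)
  r <- ct$r[ct$trait_x == "SCB" & ct$trait_y == "SG"]
  expect_lt(abs(r), 0.05)
})
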