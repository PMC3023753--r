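test_that("with zero kinship and unit weights the PK test is the two-sample t-test", {
  set.seed(42)
  n <- 12
  cl <- sprintf("c%02d", seq_len(n))
  y <- rnorm(n)
  grp <- rep(c(0, 1), each = n / 2)
  means <- means_fixture(setNames(y, cl))
  k0 <- structure(matrix(0, n, n, dimnames = list(cl, cl)),
                  class = c("kinship_matrix", "matrix"), epsilon = 0)
  fit <- fit_pk(means, k0,
                marker_values = matrix(grp, dimnames = list(cl, "m")))
  tt <- t.test(y[grp == 1], y[grp == 0], var.equal = TRUE)
  expect_equal(fit$wald_p, tt$p.value, tolerance = 1e-10)
  expect_equal(tidy(fit)$estimate[2], -unname(diff(tt$estimate)),
               tolerance = 1e-10)
  expect_equal(fit$sigma2_gtilde, 0)
})

test_that("a constant marker column raises a rank error naming it", {
  means <- means_fixture(setNames(rnorm(10), sprintf("c%02d", 1:10)))
  k <- random_kinship(10, seed = 2)
  err <- expect_error(
    fit_pk(means, k, marker_values = matrix(
      1, 10, 1, dimnames = list(sprintf("c%02d", 1:10), "flat"))),
    class = "bruisemap_rank_error")
  expect_match(conditionMessage(err), "flat")
})

test_that("profiled REML meets or beats a dense grid over the variance ratio", {
  withr::with_seed(7, {
    n <- 10
    cl <- sprintf("c%02d", seq_len(n))
    k <- random_kinship(n, seed = 7)
    r <- runif(n, 0.5, 2)
    y <- as.vector(t(chol(2 * unclass(k))) %*% rnorm(n)) +
      rnorm(n, 0, sqrt(r))
    means <- means_fixture(setNames(y, cl), se = sqrt(r))
    fit <- fit_pk(means, k)
    ctx <- fit$ctx
    grid <- 10^seq(-6, 6, length.out = 200)
    lls <- vapply(grid, function(l)
      bruisemap:::pk_profile(ctx, ctx$xbase, l), numeric(1L))
    expect_gte(fit$loglik, max(lls) - 1e-6)
  })
})

test_that("fit_pk agrees with a dense-V generic-optimizer REML", {
  withr::with_seed(15, {
    n <- 15
    cl <- sprintf("c%02d", seq_len(n))
    k <- random_kinship(n, seed = 15)
    r <- runif(n, 0.4, 3)
    y <- 2 + as.vector(t(chol(2 * unclass(k))) %*% rnorm(n, 0, 1.2)) +
      rnorm(n, 0, sqrt(r))
    means <- means_fixture(setNames(y, cl), se = sqrt(r))
    fit <- fit_pk(means, k)
    oracle <- pk_dense_oracle(y, matrix(1, n, 1), unclass(k), r)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  })
})

test_that("effects scale with the trait and p-values do not", {
  fx <- small_trial(seed = 50, n_clones = 40, n_markers = 30)
  vc <- fit_plot_model(fx$trial$plots, "BI")
  em <- adjusted_entry_means(fx$trial$plots, "BI", vc)
  k <- kinship_matrix(fx$sim$markers)
  p <- pcoa_structure(fx$sim$markers)
  sc1 <- scan_markers(em, k, p, fx$sim$markers, min_count = 3)

  em_scaled <- em
  em_scaled$estimate <- em$estimate * 3
  em_scaled$se <- em$se * 3
  attr(em_scaled, "trait") <- "BI"
  sc3 <- scan_markers(em_scaled, k, p, fx$sim$markers, min_count = 3)
  idx <- match(sc1$fragment, sc3$fragment)
  expect_equal(sc3$effect[idx], 3 * sc1$effect, tolerance = 1e-6)
  expect_equal(sc3$p_value[idx], sc1$p_value, tolerance = 1e-6)

  em_shift <- em
  em_shift$estimate <- em$estimate + 100
  sc_s <- scan_markers(em_shift, k, p, fx$sim$markers, min_count = 3)
  idx <- match(sc1$fragment, sc_s$fragment)
  expect_equal(sc_s$effect[idx], sc1$effect, tolerance = 1e-6)
  expect_equal(sc_s$p_value[idx], sc1$p_value, tolerance = 1e-6)
})

test_that("monomorphic and rare fragments are skipped with a reason", {
  fx <- small_trial(seed = 51, n_clones = 20, n_markers = 10)
  vc <- fit_plot_model(fx$trial$plots, "BI")
  em <- adjusted_entry_means(fx$trial$plots, "BI", vc)
  k <- kinship_matrix(fx$sim$markers)
  x <- as_marker_matrix(fx$sim$markers)
  x[, 1] <- 1L  # everyone carries fragment 1
  sc <- scan_markers(em, k, NULL, marker_tibble_for_test(x),
                     min_count = 3)
  skipped <- attr(sc, "skipped")
  expect_true(colnames(x)[1] %in% skipped$fragment)
  expect_match(skipped$reason[skipped$fragment == colnames(x)[1]],
               "monomorphic")
  expect_false(colnames(x)[1] %in% sc$fragment)
})

test_that("clones with a missing call are excluded for that test only", {
  fx <- small_trial(seed = 52, n_clones = 30, n_markers = 8)
  vc <- fit_plot_model(fx$trial$plots, "BI")
  em <- adjusted_entry_means(fx$trial$plots, "BI", vc)
  k <- kinship_matrix(fx$sim$markers)
  x <- as_marker_matrix(fx$sim$markers)
  x[1:4, 2] <- NA
  sc <- scan_markers(em, k, NULL, marker_tibble_for_test(x),
                     min_count = 3)
  n_used <- sc$n_used[sc$fragment == colnames(x)[2]]
  if (length(n_used)) expect_identical(n_used, 26L)
  full <- sc$n_used[sc$fragment == colnames(x)[3]]
  if (length(full)) expect_identical(full, 30L)
})

test_that("allele frequency is percent carriers among non-missing calls", {
  x <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, NA, NA), 10, 1,
              dimnames = list(sprintf("c%02d", 1:10), "f1"))
  m <- marker_tibble_for_test(x)
  expect_equal(allele_frequency(m, "f1"), 25)
  x2 <- matrix(rep(1L, 4), 4, 1,
               dimnames = list(sprintf("c%d", 1:4), "f1"))
  expect_equal(allele_frequency(marker_tibble_for_test(x2), "f1"), 100)
  x3 <- matrix(rep(0L, 4), 4, 1,
               dimnames = list(sprintf("c%d", 1:4), "f1"))
  expect_equal(allele_frequency(marker_tibble_for_test(x3), "f1"), 0)
  x4 <- matrix(NA_integer_, 4, 1,
               dimnames = list(sprintf("c%d", 1:4), "f1"))
  expect_error(allele_frequency(marker_tibble_for_test(x4), "f1"),
               class = "bruisemap_domain_error")
})

test_that("permuting trait values destroys a planted association", {
  cfg0 <- sim_config(n_clones = 60, n_markers = 40, missing_rate = 0,
                     n_environments = 3, seed = 53)
  sim <- simulate_markers(cfg0)
  x <- as_marker_matrix(sim$markers)
  target <- which.min(abs(colMeans(x) - 0.5))
  cfg <- sim_config(n_clones = 60, n_markers = 40, missing_rate = 0,
                    n_environments = 3,
                    qtl_spec = data.frame(marker = target, effect = 25),
                    seed = 53)
  trial <- simulate_trial(sim, cfg)
  vc <- fit_plot_model(trial$plots, "BI")
  em <- adjusted_entry_means(trial$plots, "BI", vc)
  k <- kinship_matrix(sim$markers)
  mv <- matrix(as.numeric(x[, target]),
               dimnames = list(rownames(x), "target"))
  p_obs <- fit_pk(em, k, marker_values = mv)$wald_p
  expect_lt(p_obs, 0.001)
  perm_p <- withr::with_seed(99, vapply(1:20, function(i) {
    emp <- em
    emp$estimate <- sample(em$estimate)
    fit_pk(emp, k, marker_values = mv)$wald_p
  }, numeric(1L)))
  expect_gt(median(perm_p), 0.05)
})

test_that("the direction flag matches the effect sign and popdev scaling", {
  fx <- small_trial(seed = 54, n_clones = 30, n_markers = 20)
  vc <- fit_plot_model(fx$trial$plots, "BI")
  em <- adjusted_entry_means(fx$trial$plots, "BI", vc)
  k <- kinship_matrix(fx$sim$markers)
  sc <- scan_markers(em, k, NULL, fx$sim$markers, min_count = 3)
  expect_identical(sc$direction,
                   ifelse(sc$effect >= 0, "increase", "decrease"))
  expect_equal(sc$effect_popdev,
               sc$effect * (1 - sc$frequency / 100), tolerance = 1e-12)
  expect_true(all(sc$frequency > 0 & sc$frequency < 100))
})

test_that("the likelihood-ratio variant agrees with Wald on clear signals", {
  fx <- small_trial(seed = 55, n_clones = 60, n_markers = 25)
  vc <- fit_plot_model(fx$trial$plots, "BI")
  em <- adjusted_entry_means(fx$trial$plots, "BI", vc)
  k <- kinship_matrix(fx$sim$markers)
  w <- scan_markers(em, k, NULL, fx$sim$markers, min_count = 3)
  l <- scan_markers(em, k, NULL, fx$sim$markers, min_count = 3,
                    test = "lr")
  expect_setequal(l$fragment, w$fragment)
  expect_true(all(l$p_value > 0 & l$p_value <= 1))
  idx <- match(w$fragment, l$fragment)
  # same ranking of evidence and close p-values on log scale
  expect_gt(cor(log(w$p_value), log(l$p_value[idx])), 0.95)
})
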