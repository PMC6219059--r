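test_that("LR statistics reproduce hand computations", {
  u <- c(1.2, -0.4, 0.8, 0.1)
  expect_equal(mu_wp(u, u), 0)
  expect_equal(mu_wp(u, u + 3), -3)          # partial minus whole
  expect_equal(slope_w_on_p(u, u), 1)
  expect_equal(slope_w_on_p(u, 0.5 * u), 0.5)  # theta_w/theta_p scaling case
  expect_equal(slope_p_on_w(u, u), 1)
  expect_equal(rho_w_p(u, u), 1)
  ch <- ebv_change(c(0, 0), c(1, -1))        # differences (+1, -1)
  expect_equal(ch$d_wp, 1)
  expect_equal(ch$vd_wp, 2)
  expect_equal(ebv_change(u, u), tibble::tibble(d_wp = 0, vd_wp = 0))
  expect_equal(predictivity(u, u), 1)
  expect_error(slope_w_on_p(rep(1, 4), u), "zero variance")
  expect_error(mu_wp(1:3, 1:4), "length")
})

test_that("null and perfect cases behave as expected", {
  set.seed(51)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(rho_w_p(a, b)), 0.05)        # independent vectors
  expect_lt(abs(predictivity(a, b)), 0.05)
  # rho2_cov: perfect evaluation u_p = u_w = u on unrelated animals
  n <- 400
  K <- diag(n); dimnames(K) <- list(sprintf("i%03d", 1:n),
                                    sprintf("i%03d", 1:n))
  vals <- replicate(200, {
    u <- rnorm(n, 0, sqrt(0.4))
    as.numeric(rho2_cov(u, u, K, sigma2_u_inf = 0.4))
  })
  expect_within_3se(vals, 1)
  # uninformative partial EBV
  u <- rnorm(n, 0, sqrt(0.4))
  expect_lt(abs(as.numeric(
    rho2_cov(rnorm(n, 0, 1e-3), u, K, sigma2_u_inf = 0.4))), 0.05)
})

test_that("rho^2 = b_wp * b_pw identity and invariances hold exactly", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    up <- rnorm(n); uw <- 0.5 * up + rnorm(n)
    expect_equal(rho_w_p(up, uw)^2,
                 slope_w_on_p(up, uw) * slope_p_on_w(up, uw),
                 tolerance = 1e-10)
  }
  # location invariance: constants shift only mu_wp
  up <- rnorm(50); uw <- rnorm(50)
  expect_equal(mu_wp(up + 2, uw), mu_wp(up, uw) + 2)
  expect_equal(slope_w_on_p(up + 2, uw - 1), slope_w_on_p(up, uw))
  expect_equal(rho_w_p(up + 2, uw - 1), rho_w_p(up, uw))
  # theta-scaling law: b_wp scales by theta_w/theta_p, rho unchanged
  theta_p <- 1.7; theta_w <- 1.2
  expect_equal(slope_w_on_p(theta_p * up, theta_w * uw),
               (theta_w / theta_p) * slope_w_on_p(up, uw),
               tolerance = 1e-12)
  expect_equal(slope_p_on_w(theta_p * up, theta_w * uw),
               (theta_p / theta_w) * slope_p_on_w(up, uw),
               tolerance = 1e-12)
  expect_equal(rho_w_p(theta_p * up, theta_w * uw), rho_w_p(up, uw),
               tolerance = 1e-12)
})

test_that("accuracy conversions match the published dairy example", {
  # r = 0.30, h2 = 0.30 (base) and h2_inf = 0.20 (selected equilibrium)
  expect_equal(round(as.numeric(acc_from_predictivity(0.30, sqrt(0.30))), 2),
               0.55)
  expect_equal(round(as.numeric(acc_from_predictivity(0.30, sqrt(0.20))), 2),
               0.67)
  expect_equal(as.numeric(acc_from_predictivity(0, 0.5)), 0)
  expect_true(attr(acc_from_predictivity(0.9, 0.5), "out_of_range"))
  # h2_inf = 0.20 from sigma2_u_inf = 0.18, sigma2_e = 0.70
  vc_dairy <- variance_components(0.30, 0.70, sigma2_u_inf = 0.18)
  expect_equal(round(vc_dairy$h2_inf, 2), 0.20)
  expect_equal(round(vc_dairy$k, 1), 0.4)
  # translation to the unselected scale: 0.67 -> 0.82 with k = 0.4
  expect_equal(round(selected_to_unselected_acc(0.67, 0.4), 2), 0.82)
  expect_equal(selected_to_unselected_acc(0.5, 0), 0.5)  # k = 0 identity
  expect_equal(selected_to_unselected_acc(1, 0.3), 1)
})

test_that("selected-to-unselected conversion is validated by equilibrium selection simulation", {
  # Monte-Carlo: bivariate (u, u_hat) with corr acc_sel on the reduced
  # variance scale; restoring the removed between-family variance (variance
  # k*s2 independent of the prediction error) gives the unselected-scale
  # correlation sqrt(k + (1-k) acc_sel^2).
  set.seed(53)
  acc_sel <- 0.67; k <- 0.4; s2 <- 1
  n <- 2e5
  uhat <- rnorm(n, 0, sqrt((1 - k) * s2) * acc_sel)
  u_inf <- uhat + rnorm(n, 0, sqrt((1 - k) * s2 * (1 - acc_sel^2)))
  trend <- rnorm(n, 0, sqrt(k * s2))  # genetic-level differences removed
  u_base <- u_inf + trend             # by selection, known without error
  r_sel <- cor(u_inf, uhat)
  r_base <- cor(u_base, uhat + trend)
  expect_equal(r_sel, acc_sel, tolerance = 0.01)
  expect_equal(r_base, selected_to_unselected_acc(acc_sel, k),
               tolerance = 0.01)
})

test_that("precorrection inflation matches the balanced-design formula", {
  expect_equal(round(100 * precorrection_inflation(500, 25), 2), 5.04)
  expect_equal(precorrection_inflation(500, 1), 0)
  # n large, m not small: approximately 1/n_i with n_i = n/m
  expect_equal(precorrection_inflation(10000, 100), 1 / (10000 / 100),
               tolerance = 0.02)
  expect_error(precorrection_inflation(10, 12))
})

test_that("young-bull counterexample matches a Monte-Carlo selection-index oracle", {
  h2 <- 0.25
  # closed-form limits
  yb <- young_bull_counterexample(c(0, 1e9), h2)
  expect_equal(yb$cov_pw[1], 0)
  expect_equal(yb$cov_pw[2], yb$var_p[2], tolerance = 1e-6)
  # cov < var for finite n
  yb2 <- young_bull_counterexample(c(1, 5, 20, 1000), h2)
  expect_true(all(yb2$cov_pw < yb2$var_p))
  expect_true(all(diff(yb2$cov_pw) > 0))

  # Monte-Carlo oracle: simulate dam record and n progeny means, build both
  # index EBV from empirical regressions, measure cov and var
  set.seed(54)
  R <- 1e6
  for (n in c(1, 5, 20)) {
    u_dam <- rnorm(R, 0, sqrt(h2))
    u_bull <- 0.5 * u_dam + rnorm(R, 0, sqrt(0.75 * h2))
    y_dam <- u_dam + rnorm(R, 0, sqrt(1 - h2))
    # n progeny from n distinct mates, phenotypic variance 1
    u_prog_mean <- 0.5 * u_bull +
      rnorm(R, 0, sqrt((0.25 * h2 + 0.5 * h2 + (1 - h2)) / n))
    b1 <- cov(u_bull, y_dam) / var(y_dam)
    b2 <- cov(u_bull, u_prog_mean) / var(u_prog_mean)
    u_p <- b1 * y_dam
    u_w <- b2 * u_prog_mean
    closed <- young_bull_counterexample(n, h2)
    expect_equal(cov(u_p, u_w), closed$cov_pw, tolerance = 0.05,
                 label = paste("cov, n =", n))
    expect_equal(var(u_p), closed$var_p, tolerance = 0.02,
                 label = paste("var, n =", n))
  }
})

test_that("lr_stats computes the statistics per subset from a pair table", {
  set.seed(55)
  K <- nrm(random_family_pedigree(5, 4))
  ids <- grep("^O", rownames(K), value = TRUE)
  up <- rnorm(length(ids)); uw <- up + rnorm(length(ids), 0, 0.3)
  pair <- tibble::tibble(
    id = ids, ebv_partial = up, ebv_whole = uw,
    subset = rep(c("reference", "validation"), length.out = length(ids)),
    y_star = uw + rnorm(length(ids)))
  out <- lr_stats(pair, K = K, sigma2_u_inf = 0.4)
  expect_equal(out$subset, c("all", "reference", "validation"))
  expect_true(all(c("mu_wp", "b_wp", "b_pw", "rho_wp", "rho2_cov", "d_wp",
                    "vd_wp", "predictivity") %in% names(out)))
  # subset rows recompute with subset means
  v <- pair$subset == "validation"
  expect_equal(out$b_wp[3], slope_w_on_p(up[v], uw[v]))
  expect_equal(out$rho_wp[2], rho_w_p(up[!v], uw[!v]))
  expect_error(lr_stats(pair[, 1:2]), "missing column")
})
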