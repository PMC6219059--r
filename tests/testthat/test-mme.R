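test_that("MME solutions match closed forms", {
  # one animal, one record, overall mean: 2x2 system [[1,1],[1,1+lambda]]
  K1 <- matrix(1, 1, 1, dimnames = list("a", "a"))
  fit <- solve_mme(data.frame(id = "a", y = 3), K1, vc04)
  expect_equal(unname(fit$beta), 3)
  expect_equal(unname(fit$u), 0)

  # unrelated animals, no fixed effects: ridge shrinkage y/(1+lambda)
  set.seed(41)
  n <- 12
  Kn <- diag(n); dimnames(Kn) <- list(sprintf("i%02d", 1:n),
                                      sprintf("i%02d", 1:n))
  y <- rnorm(n)
  fit2 <- solve_mme(data.frame(id = sprintf("i%02d", 1:n), y = y), Kn, vc04,
                    fixed = ~0)
  expect_equal(unname(fit2$u), y / (1 + vc04$lambda), tolerance = 1e-10)

  # animal without records: parent average when parents carry the information
  ped <- trio_pedigree()
  K <- nrm(ped)
  ph <- data.frame(id = rep(c("s", "d"), each = 25), y = rnorm(50))
  fit3 <- solve_mme(ph, K, vc04, fixed = ~0)
  expect_equal(unname(fit3$u["o"]),
               unname(0.5 * (fit3$u["s"] + fit3$u["d"])), tolerance = 1e-10)
  # dense-inverse oracle on the same system
  lambda <- vc04$lambda
  Z <- matrix(0, 50, 3, dimnames = list(NULL, c("s", "d", "o")))
  Z[cbind(1:50, match(ph$id, colnames(Z)))] <- 1
  LHS <- crossprod(Z) + solve(K) * lambda
  expect_equal(unname(fit3$u[colnames(Z)]),
               unname(drop(solve(LHS, crossprod(Z, ph$y)))),
               tolerance = 1e-10)
})

test_that("single records on unrelated animals give acc^2 = h2 per animal", {
  n <- 6
  Kn <- diag(n); dimnames(Kn) <- list(letters[1:n], letters[1:n])
  fit <- solve_mme(data.frame(id = letters[1:n], y = rnorm(n)), Kn, vc04,
                   fixed = ~0)
  # PEV = sigma2_u sigma2_e / (sigma2_u + sigma2_e)
  expect_equal(unname(diag(fit$C_uu)),
               rep(vc04$sigma2_u * vc04$sigma2_e /
                     (vc04$sigma2_u + vc04$sigma2_e), n), tolerance = 1e-10)
  acc <- individual_accuracy(fit, Kn)
  expect_equal(acc$accuracy, rep(sqrt(vc04$h2), n), tolerance = 1e-10)
})

test_that("solver errors are informative", {
  K1 <- matrix(1, 1, 1, dimnames = list("a", "a"))
  # confounded fixed effects
  d <- data.frame(id = c("a", "a"), y = c(1, 2),
                  f1 = factor(c("x", "y")), f2 = factor(c("u", "v")))
  expect_error(solve_mme(d, K1, vc04, fixed = ~ f1 + f2), "rank deficient")
  # singular K
  K2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(solve_mme(data.frame(id = c("a", "b"), y = 1:2), K2, vc04),
               "ridge")
  # id missing from K
  expect_error(solve_mme(data.frame(id = "zz", y = 1), K1, vc04), "zz")
})

test_that("population accuracy from PEV has correct limits and flags", {
  K <- nrm(fullsib_pedigree(4))
  focal <- sprintf("o%02d", 1:4)
  base <- list(vc = vc04, C_uu = K * vc04$sigma2_u)
  class(base) <- "blup_fit"
  # no data: C_uu = K sigma2_u -> acc = 0
  expect_equal(as.numeric(accuracy_from_pev(base, K, vc04, focal)), 0)
  # perfect evaluation: C_uu = 0 -> acc = 1
  perfect <- base; perfect$C_uu <- K * 0
  expect_equal(as.numeric(accuracy_from_pev(perfect, K, vc04, focal)), 1)
  # single-individual focal set is undefined
  expect_error(accuracy_from_pev(base, K, vc04, focal = "o01"), "undefined")
})

test_that("theoretical accuracy matches empirical corr(u, u_hat) on simulation", {
  set.seed(42)
  ped <- random_family_pedigree(n_fam = 20, sibs = 5)
  K <- nrm(ped)
  F <- inbreeding(ped)$F
  focal <- grep("^O", ped$id, value = TRUE)
  sys <- lrcv:::mme_build(data.frame(id = focal, y = 0), K, vc04, fixed = ~1)
  Cinv <- lrcv:::mme_inverse(sys)
  ui <- sys$p + seq_len(sys$q)
  fit <- structure(list(vc = vc04,
                        C_uu = vc04$sigma2_e * Cinv[ui, ui]), class = "blup_fit")
  dimnames(fit$C_uu) <- list(sys$ids, sys$ids)
  acc_theory <- as.numeric(accuracy_from_pev(fit, K, vc04, focal))
  cors <- replicate(500, {
    u <- simulate_tbv(ped, vc04$sigma2_u, F = F)
    y <- u[focal] + rnorm(length(focal), 0, sqrt(vc04$sigma2_e))
    sol <- lrcv:::mme_solve_y(sys, y)
    cor(u[focal], sol$u[focal])
  })
  expect_within_3se(cors, acc_theory)
})

test_that("precorrection reproduces GLS and is invariant to the constraint", {
  set.seed(43)
  # toy 6-record, 2-level dataset on related animals
  ped <- fullsib_pedigree(6)
  K <- nrm(ped)
  ids <- sprintf("o%02d", 1:6)
  d <- data.frame(id = ids, y = rnorm(6, 2), lev = factor(rep(c("A", "B"), 3)))
  fit <- solve_mme(d, K, vc04, fixed = ~lev)
  ystar <- precorrect(d, fit)$y_star
  # oracle: direct GLS with V = Z K Z' sigma2_u + I sigma2_e
  Z <- matrix(0, 6, nrow(ped)); Z[cbind(1:6, match(ids, ped$id))] <- 1
  V <- Z %*% K %*% t(Z) * vc04$sigma2_u + diag(6) * vc04$sigma2_e
  X <- model.matrix(~lev, d)
  beta_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, d$y))
  expect_equal(ystar, unname(d$y - drop(X %*% beta_gls)), tolerance = 1e-8)
  # changing the treatment constraint (reference level) leaves y* unchanged
  d2 <- d; d2$lev <- relevel(d2$lev, "B")
  fit2 <- solve_mme(d2, K, vc04, fixed = ~lev)
  expect_equal(precorrect(d2, fit2)$y_star, ystar, tolerance = 1e-8)
  # beta = 0 -> y* = y
  fit0 <- fit; fit0$beta[] <- 0
  expect_equal(precorrect(d, fit0)$y_star, d$y)
  # unseen level errors
  d3 <- d; d3$lev <- factor(rep("C", 6))
  expect_error(precorrect(d3, fit), "precorrection")
})

test_that("EM-REML matches lme4 REML on a random-intercept design", {
  set.seed(46)
  n <- 60; reps <- 4
  ids <- sprintf("i%03d", seq_len(n))
  u <- rnorm(n, 0, sqrt(0.4))
  d <- data.frame(id = rep(ids, each = reps))
  d$y <- 2 + u[match(d$id, ids)] + rnorm(nrow(d), 0, sqrt(0.6))
  K <- diag(n); dimnames(K) <- list(ids, ids)
  est <- em_reml(d, K, start = variance_components(0.2, 0.8),
                 max_iter = 2000)
  m <- lme4::lmer(y ~ 1 + (1 | id), data = d, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(est$sigma2_u, vcs[1], tolerance = 1e-4)
  expect_equal(est$sigma2_e, vcs[2], tolerance = 1e-4)
})

test_that("EM-REML recovers simulated variance components", {
  set.seed(44)
  errs <- replicate(8, {
    ped <- random_family_pedigree(n_fam = 40, sibs = 4)
    K <- nrm(ped)
    F <- inbreeding(ped)$F
    u <- simulate_tbv(ped, 0.4, F = F)
    # every animal with two records
    d <- data.frame(id = rep(ped$id, 2))
    d$y <- 1 + u[d$id] + rnorm(nrow(d), 0, sqrt(0.6))
    est <- em_reml(d, K, start = variance_components(0.25, 0.75),
                   max_iter = 3000)
    est$h2 - 0.4
  })
  expect_lt(abs(median(errs)), 0.1)
})

test_that("EM-REML flags boundary collapse and errors on non-convergence", {
  set.seed(45)
  n <- 50; reps <- 3
  ids <- sprintf("i%02d", seq_len(n))
  Kn <- diag(n); dimnames(Kn) <- list(ids, ids)
  d <- data.frame(id = rep(ids, each = reps))
  d$y <- rnorm(nrow(d))  # h2 = 0: no between-animal variance
  est <- em_reml(d, Kn, start = variance_components(0.5, 0.5),
                 max_iter = 5000)
  expect_lt(est$h2, 0.15)
  expect_error(
    em_reml(d, Kn, start = variance_components(0.5, 0.5), max_iter = 3),
    "did not converge")
})
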