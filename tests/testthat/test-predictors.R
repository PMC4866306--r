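test_that("phenotype regression reproduces exact linear relations", {
  # 3-point worked example: y = 1 + x
  fit <- fit_phenotype_regression(matrix(c(0, 1, 2), ncol = 1,
                                         dimnames = list(NULL, "p1")),
                                  c(1, 2, 3))
  expect_equal(unname(fit$beta), 1)
  expect_equal(unname(fit$intercept), 1)

  # y equal to one covariate: that weight 1, others 0, in-sample R^2 = 1
  set.seed(7)
  P <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("p", 1:3)))
  y <- P[, 2]
  fit2 <- fit_phenotype_regression(P, y)
  expect_equal(unname(fit2$beta), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(r2_score(y, predict(fit2, P)), 1, tolerance = 1e-10)

  # y independent of P: out-of-sample R^2 near zero
  set.seed(8)
  P <- matrix(rnorm(2000), 500, 4, dimnames = list(NULL, paste0("p", 1:4)))
  y <- rnorm(500)
  fit3 <- fit_phenotype_regression(P[1:250, ], y[1:250])
  expect_lt(abs(r2_score(y[251:500], predict(fit3, P[251:500, ]))), 0.1)

  # rank deficiency: duplicated covariate -> warning, minimum-norm fit
  Pd <- cbind(P[, 1], P[, 1])
  colnames(Pd) <- c("a", "b")
  expect_warning(fit_phenotype_regression(Pd, y), "minimum-norm")
  expect_error(fit_phenotype_regression(P[1:10, ], y[1:5]),
               class = "dgp_argument_error")
})

test_that("variance components maximize the stated likelihood", {
  set.seed(21)
  n <- 80
  Z <- matrix(rnorm(n * 30), n, 30)
  K <- tcrossprod(Z); K <- K / mean(diag(K))
  # dense-likelihood grid oracle over the variance ratio
  dense_profile_loglik <- function(delta, K, y) {
    n <- length(y)
    V0 <- K + diag(delta, n)
    Vinv_1 <- solve(V0, rep(1, n))
    mu <- sum(Vinv_1 * y) / sum(Vinv_1)
    r <- y - mu
    sg <- sum(r * solve(V0, r)) / n
    -0.5 * (n * log(2 * pi) + n * log(sg) +
              determinant(V0)$modulus[1] + n)
  }
  y <- as.vector(chol(2 * K + diag(0.5, n)) %*% rnorm(n))
  vc <- fit_variance_components(K, y)
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 100))
  grid_ll <- vapply(grid, dense_profile_loglik, numeric(1), K = K, y = y)
  expect_gte(vc$loglik, max(grid_ll) - 1e-6)
  expect_equal(vc$loglik,
               dense_profile_loglik(vc$sigma_e2 / vc$sigma_g2, K, y),
               tolerance = 1e-8)

  # pure i.i.d. noise: h2 near zero
  set.seed(22)
  h2_null <- fit_variance_components(K, rnorm(n))$h2
  expect_lt(h2_null, 0.25)

  # constant y: sigma_g2 = 0 with a warning
  expect_warning(vc0 <- fit_variance_components(K, rep(3, n)), "constant")
  expect_equal(vc0$sigma_g2, 0)
})

test_that("variance ratio recovery on data simulated from the model", {
  # y ~ N(0, 4K + 1I): h2 = 0.8; recovery within 0.05 averaged over 5 seeds
  n <- 1000
  set.seed(31)
  Z <- matrix(rnorm(n * 400), n, 400)
  K <- tcrossprod(Z); K <- K / mean(diag(K))
  R <- chol(4 * K + diag(1, n))
  h2s <- vapply(1:5, function(s) {
    set.seed(100 + s)
    y <- as.vector(crossprod(R, rnorm(n)))
    fit_variance_components(K, y)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.8), 0.05)
})

test_that("BLUP conditioning matches closed forms and the dense oracle", {
  # K = I: no relatedness, prediction = mu, conditional variance = sigma_g2
  ids <- paste0("i", 1:6)
  K_I <- diag(6); dimnames(K_I) <- list(ids, ids)
  vc <- structure(list(sigma_g2 = 2, sigma_e2 = 0.5, mu = 1.3, h2 = 0.8),
                  class = "varcomp")
  y_tr <- c(0.2, 1.8, 0.9, 2.4)
  bp <- blup_predict(K_I, y_tr, ids[1:4], ids[5:6], vc = vc)
  expect_equal(bp$pred_mean, rep(1.3, 2))
  expect_equal(bp$pred_sd, rep(sqrt(2 + 0.5), 2))

  # sigma_e2 -> 0 and duplicated K row: prediction equals that phenotype
  set.seed(12)
  Z <- matrix(rnorm(6 * 20), 6, 20)
  Z[6, ] <- Z[1, ]  # test individual genetically identical to train ind. 1
  Kd <- tcrossprod(Z) / mean(diag(tcrossprod(Z)))
  dimnames(Kd) <- list(ids, ids)
  vc0 <- structure(list(sigma_g2 = 1, sigma_e2 = 1e-12, mu = 0, h2 = 1),
                   class = "varcomp")
  y5 <- c(1.1, -0.4, 0.8, 0.3, 2.2)
  bp0 <- blup_predict(Kd, y5, ids[1:5], ids[6], vc = vc0)
  expect_equal(bp0$pred_mean, y5[1], tolerance = 1e-5)

  # 6-individual instance against the brute-force Schur oracle
  set.seed(13)
  Z <- matrix(rnorm(6 * 15), 6, 15)
  K6 <- tcrossprod(Z) / mean(diag(tcrossprod(Z)))
  dimnames(K6) <- list(ids, ids)
  vc6 <- structure(list(sigma_g2 = 1.7, sigma_e2 = 0.6, mu = -0.2, h2 = NA),
                   class = "varcomp")
  y4 <- c(0.5, -1.2, 0.3, 1.9)
  bp6 <- blup_predict(K6, y4, ids[1:4], ids[5:6], vc = vc6,
                      include_residual = FALSE)
  # oracle: joint (g_test, y_train) covariance blocks
  V <- 1.7 * K6
  V[1:4, 1:4] <- V[1:4, 1:4] + diag(0.6, 4)  # training phenotype block
  orc <- mvn_condition_oracle(rep(-0.2, 6), V, 1:4, 5:6, y4)
  expect_equal(bp6$pred_mean, orc$mean, tolerance = 1e-8)
  expect_equal(bp6$pred_sd, orc$sd, tolerance = 1e-8)

  # predictive SD never exceeds the marginal SD
  bp6r <- blup_predict(K6, y4, ids[1:4], ids[5:6], vc = vc6)
  expect_true(all(bp6r$pred_sd <= sqrt(1.7 * max(diag(K6)) + 0.6) + 1e-8))
  expect_error(blup_predict(K6, y4, ids[1:4], ids[4:5], vc = vc6),
               class = "dgp_argument_error")
})

test_that("repeatability follows its defining formula", {
  # hand-computed example: A:(1,3), B:(2,2) -> sigma2 = 0.5 = Var(r), H2 = 0
  ph <- tibble::tibble(hybrid_id = c("A", "A", "B", "B"), trait = "t",
                       replicate = c(1L, 2L, 1L, 2L), value = c(1, 3, 2, 2))
  rp <- estimate_repeatability(ph, "t")
  expect_equal(rp$H2_single, 0)
  expect_equal(rp$H2_mean, 0)

  # i.i.d. noise, no individual effect: repeatability near zero
  set.seed(5)
  ph2 <- tidyr::expand_grid(hybrid_id = paste0("h", 1:400),
                            replicate = 1:4) |>
    dplyr::mutate(trait = "t", value = rnorm(1600))
  expect_lt(estimate_repeatability(ph2, "t")$H2_single, 0.12)

  expect_error(estimate_repeatability(ph[c(1, 3), ], "t"),
               class = "dgp_argument_error")
  expect_error(estimate_repeatability(ph, "nope"),
               class = "dgp_argument_error")
})

test_that("midparent prediction solves the additive two-way layout", {
  d <- small_diallel()
  ped <- d$pedigree
  # noiseless additive layout y_ij = a_i + b_j: exact recovery
  a <- stats::setNames(rnorm(10), unique(ped$parent_a))
  b <- stats::setNames(rnorm(10), unique(ped$parent_alpha))
  y <- a[ped$parent_a] + b[ped$parent_alpha]
  # hold out the diagonal so every parent stays represented in training
  te <- paste0(sprintf("A%03d", 1:10), "x", sprintf("L%03d", 1:10))
  tr <- setdiff(ped$hybrid_id, te)
  mp <- fit_midparent(ped, y[match(tr, ped$hybrid_id)], tr)
  pr <- predict_midparent(mp, ped, te)
  expect_equal(pr$pred_mean, unname(y[match(te, ped$hybrid_id)]),
               tolerance = 1e-8)

  # midparent invariant: prediction = (P1_i + P2_j) / 2
  p1 <- mp$parents_a$value[match(ped$parent_a[match(te, ped$hybrid_id)],
                                 mp$parents_a$parent)]
  p2 <- mp$parents_alpha$value[match(ped$parent_alpha[match(te, ped$hybrid_id)],
                                     mp$parents_alpha$parent)]
  expect_equal(pr$pred_mean, (p1 + p2) / 2)

  # 2x2 diallel, one held-out cell, against the normal-equations oracle
  ped2 <- tibble::tibble(hybrid_id = c("11", "12", "21", "22"),
                         parent_a = c("A1", "A1", "A2", "A2"),
                         parent_alpha = c("L1", "L2", "L1", "L2"))
  y2 <- c(0, 2, 2, 4)
  mp2 <- fit_midparent(ped2, y2[1:3], ped2$hybrid_id[1:3])
  X <- cbind(1, c(0, 0, 1), c(0, 1, 0))  # intercept, a2 dummy, l2 dummy
  beta <- solve(crossprod(X), crossprod(X, y2[1:3]))
  oracle_22 <- beta[1] + beta[2] + beta[3]
  expect_equal(predict_midparent(mp2, ped2, "22")$pred_mean,
               unname(oracle_22))

  # unseen parent -> NA prediction with warning
  expect_warning(pr_na <- predict_midparent(mp2, ped2, "22"), NA)
  mp3 <- fit_midparent(ped2, y2[1:2], ped2$hybrid_id[1:2])
  expect_warning(pr3 <- predict_midparent(mp3, ped2, c("21", "22")), "unseen")
  expect_true(all(is.na(pr3$pred_mean)))
})

test_that("midparent and BLUP nearly coincide on fully additive traits", {
  d <- small_diallel()
  sites <- colnames(d$G)
  set.seed(9)
  arch <- trait_architecture(list(list(
    trait = "add",
    additive = tibble::tibble(site_id = sample(sites, 25), beta = rnorm(25)),
    resid_sd = 0.1, rep_sd = 0.1)))
  ph <- simulate_phenotypes(d$G, arch, 4, seed = 10)
  Y <- phenotype_matrix(ph, d$pedigree$hybrid_id)
  plan <- build_cv_folds(d$pedigree, seed = 2)
  te <- plan$hybrid_id[plan$fold == 1]
  tr <- setdiff(d$pedigree$hybrid_id, te)
  K <- compute_grm(d$G)
  blup <- blup_predict(K, Y[tr, 1], tr, te)
  mp <- predict_midparent(fit_midparent(d$pedigree, Y[tr, 1], tr),
                          d$pedigree, te)
  expect_gt(cor(blup$pred_mean, mp$pred_mean)^2, 0.95)
})
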