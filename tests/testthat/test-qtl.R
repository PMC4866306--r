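test_that("forward selection finds planted signal and matches brute force", {
  d <- small_diallel()
  G <- d$G[1:30, 1:5]
  storage.mode(G) <- "double"

  # one causal site, zero noise: selected first, residual SS zero
  y <- 2 * G[, 3]
  path <- forward_select_terms(G, y, max_terms = 3)
  expect_equal(path$term[1], colnames(G)[3])
  expect_lt(path$rss[1], 1e-16)

  # greedy path equals an exhaustive per-step search oracle
  set.seed(14)
  y2 <- G[, 1] - 0.5 * G[, 4] + rnorm(30, sd = 0.5)
  path2 <- forward_select_terms(G, y2, max_terms = 4)
  chosen <- character(0)
  for (step in 1:4) {
    rss <- vapply(setdiff(colnames(G), chosen), function(cand) {
      X <- cbind(1, G[, c(chosen, cand), drop = FALSE])
      sum(stats::lm.fit(X, y2)$residuals^2)
    }, numeric(1))
    chosen <- c(chosen, names(which.min(rss)))
  }
  expect_equal(path2$term, chosen)

  expect_error(forward_select_terms(G[, 0], y), class = "dgp_argument_error")
})

test_that("orthogonal candidates are selected by marginal correlation", {
  set.seed(15)
  Q <- qr.Q(qr(matrix(rnorm(40 * 6), 40, 6)))
  X <- Q[, 2:6]  # orthogonal columns
  X <- sweep(X, 2, colMeans(X))  # centred: orthogonality preserved approx
  X <- qr.Q(qr(cbind(1, X)))[, -1]  # orthogonal to the intercept too
  colnames(X) <- paste0("c", 1:5)
  y <- rnorm(40)
  path <- forward_select_terms(X, y, max_terms = 5)
  marg <- abs(cor(X, y))
  expect_equal(path$term, colnames(X)[order(-marg)])
})

test_that("model size selection follows the inner-CV curve", {
  d <- small_diallel()
  G <- d$G
  storage.mode(G) <- "double"

  # monogenic noiseless trait: chosen size 1
  y <- 1.5 * G[, 7]
  fit <- fit_qtl_model(G, y, max_terms = 10, seed = 3)
  expect_equal(fit$n_terms, 1)
  expect_equal(fit$terms, colnames(G)[7])
  expect_equal(unname(fit$coef["(Intercept)"]), 0, tolerance = 1e-10)

  # pure-noise response: the sized model has near-zero inner-CV R^2, and the
  # chosen size never does worse than the empty model
  set.seed(16)
  yn <- rnorm(nrow(G))
  Xp <- G[, forward_select_terms(G, yn, max_terms = 10)$term]
  m <- select_model_size(Xp, yn, n_folds = 4, seed = 5)
  best <- m$cv$mean_r2[m$cv$size == m$n_terms]
  expect_gte(best, m$cv$mean_r2[m$cv$size == 0] - 1e-12)
  expect_lte(best, 0.05)

  # inner-CV curve matches an independent fold-loop oracle
  folds <- diallelGP::derive_seed(5, "inner-cv")
  set.seed(folds)
  f_assign <- sample(rep(1:4, length.out = nrow(Xp)))
  oracle <- sapply(0:ncol(Xp), function(t) {
    mean(vapply(1:4, function(f) {
      tr <- f_assign != f
      Xd <- cbind(1, Xp[, seq_len(t), drop = FALSE])
      beta <- qr.coef(qr(Xd[tr, , drop = FALSE]), yn[tr])
      beta[is.na(beta)] <- 0
      r2_score(yn[!tr], as.vector(Xd[!tr, , drop = FALSE] %*% beta))
    }, numeric(1)))
  })
  expect_equal(m$cv$mean_r2, unname(oracle), tolerance = 1e-10)

  expect_error(select_model_size(Xp, yn, n_folds = nrow(Xp) + 1),
               class = "dgp_argument_error")
})

test_that("interaction candidates expand from selected additive terms", {
  expect_setequal(expand_interaction_candidates("a", c("a", "b")),
                  c("a:a", "a:b"))
  # self-pair column is the squared dosage
  G <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "a"))
  expect_equal(unname(diallelGP:::term_columns(G, "a:a")[, 1]), c(0, 1, 4))
  expect_error(expand_interaction_candidates(character(0), "a"),
               class = "dgp_argument_error")
})

test_that("self-interaction captures an overdominant locus", {
  d <- small_diallel()
  G <- d$G
  site <- colnames(G)[5]
  y <- as.numeric(G[, site] == 1)  # pure heterozygote advantage
  rss_add <- sum(stats::lm.fit(cbind(1, G[, site]), y)$residuals^2)
  rss_dom <- sum(stats::lm.fit(cbind(1, G[, site], G[, site]^2), y)$residuals^2)
  expect_lt(rss_dom, rss_add - 1e-8)
  # the sized interaction model picks up the dominance term
  fit <- fit_qtl_model(G, y + rnorm(nrow(G), sd = 0.05), max_terms = 5,
                       interactions = TRUE, max_int_terms = 3, seed = 8)
  expect_true(any(grepl(":", fit$terms)))
})

test_that("the LMM reduces to BLUP and to OLS in its limiting cases", {
  d <- small_diallel()
  Y <- phenotype_matrix(d$phenotypes, d$pedigree$hybrid_id)
  K <- compute_grm(d$G)
  tr <- d$pedigree$hybrid_id[1:70]
  te <- setdiff(d$pedigree$hybrid_id, tr)[1:10]
  y_tr <- Y[tr, 1]

  # no fixed terms: identical to blup_predict
  empty_fix <- diallelGP:::fit_qtl_weights(
    matrix(0, length(tr), 0, dimnames = list(tr, NULL)), y_tr)
  lmm0 <- fit_lmm(d$G, K, y_tr, tr, fixed = empty_fix)
  p0 <- predict(lmm0, d$G, te)
  bp <- blup_predict(K, y_tr, tr, te)
  expect_equal(p0$pred_mean, bp$pred_mean, tolerance = 1e-10)
  expect_equal(p0$pred_sd, bp$pred_sd, tolerance = 1e-10)

  # sigma_g2 = 0: identical to OLS on the fixed effects
  qfit <- fit_qtl_model(d$G[tr, ], y_tr, max_terms = 5, seed = 2)
  lmm1 <- fit_lmm(d$G, K, y_tr, tr, fixed = qfit)
  lmm1$vc <- structure(list(sigma_g2 = 0, sigma_e2 = lmm1$vc$sigma_e2,
                            mu = mean(lmm1$resid_train), h2 = 0),
                       class = "varcomp")
  p1 <- predict(lmm1, d$G, te)
  expect_equal(p1$pred_mean, predict(qfit, d$G[te, ]), tolerance = 1e-10)
})

test_that("LMM conditioning matches the dense MVN oracle on small instances", {
  d <- small_diallel()
  ids <- d$pedigree$hybrid_id[1:10]
  K10 <- compute_grm(d$G[ids, ])
  y <- phenotype_matrix(d$phenotypes, ids)[, 2]
  tr <- ids[1:7]; te <- ids[8:10]
  qfit <- fit_qtl_model(d$G[tr, ], y[tr], max_terms = 2, seed = 4)
  lmm <- fit_lmm(d$G, K10, y[tr], tr, fixed = qfit)
  pr <- predict(lmm, d$G, te)
  # oracle: fixed part + dense conditioning of the residual MVN
  fx_tr <- predict(qfit, d$G[tr, ]) - qfit$coef[1]
  fx_te <- predict(qfit, d$G[te, ]) - qfit$coef[1]
  vc <- lmm$vc
  V <- vc$sigma_g2 * K10$K
  V[1:7, 1:7] <- V[1:7, 1:7] + diag(vc$sigma_e2, 7)
  orc <- mvn_condition_oracle(rep(vc$mu, 10), V, 1:7, 8:10, y[tr] - fx_tr)
  expect_equal(pr$pred_mean, fx_te + orc$mean, tolerance = 1e-8)
  expect_equal(pr$pred_sd, sqrt(orc$sd^2 + vc$sigma_e2), tolerance = 1e-8)
})

test_that("the phenotype stage of LMM+P behaves at its limits", {
  d <- small_diallel()
  Y <- phenotype_matrix(d$phenotypes, d$pedigree$hybrid_id)
  K <- compute_grm(d$G)
  tr <- d$pedigree$hybrid_id[1:70]
  te <- setdiff(d$pedigree$hybrid_id, tr)[1:15]
  y_tr <- Y[tr, 1]

  # a zero-weight covariate stage: predictions reduce exactly to the plain
  # LMM's (an uninformative constant covariate gets weight zero, so stage 1
  # only recentres)
  P_const <- matrix(1, nrow(Y), 1, dimnames = list(rownames(Y), "q1"))
  suppressWarnings(
    lp <- fit_lmm_plus_p(P_const[tr, , drop = FALSE], y_tr, d$G, K, tr,
                         max_terms = 5, seed = 2))
  lm0 <- fit_lmm(d$G, K, y_tr, tr, max_terms = 5, seed = 2)
  expect_equal(predict(lp, d$G, P_const[te, , drop = FALSE], te)$pred_mean,
               predict(lm0, d$G, te)$pred_mean, tolerance = 1e-8)

  # response leaked as a covariate: stage 1 is exact, stage 2 inert
  set.seed(33)
  P_ind <- matrix(rnorm(nrow(Y) * 2), ncol = 2,
                  dimnames = list(rownames(Y), c("q1", "q2")))
  P_leak <- cbind(P_ind, leak = Y[, 1])[, c(3, 1)]
  # stage-2 residuals are (numerically) constant, which fit_variance_components
  # flags; that degenerate path is exactly what this check exercises
  expect_warning(
    lp2 <- fit_lmm_plus_p(P_leak[tr, ], y_tr, d$G, K, tr, max_terms = 5,
                          seed = 2),
    "constant phenotype")
  expect_lt(max(abs(lp2$stage2$resid_train)), 1e-8)
  expect_equal(predict(lp2, d$G, P_leak[te, ], te)$pred_mean,
               unname(Y[te, 1]), tolerance = 1e-6)
})

test_that("multi-trait conditioning matches single-trait and dense oracles", {
  ids <- paste0("i", 1:8)
  set.seed(44)
  Z <- matrix(rnorm(8 * 30), 8, 30)
  K <- tcrossprod(Z) / mean(diag(tcrossprod(Z)))
  dimnames(K) <- list(ids, ids)
  C <- matrix(c(1.2, 0.6, 0.6, 0.9), 2,
              dimnames = list(c("t1", "t2"), c("t1", "t2")))
  S <- matrix(c(0.4, 0.15, 0.15, 0.3), 2, dimnames = dimnames(C))
  V <- kronecker(C, K) + kronecker(S, diag(8))
  y_vec <- as.vector(chol(V) %*% rnorm(16))
  Y <- matrix(y_vec, 8, 2, dimnames = list(ids, c("t1", "t2")))
  Fm <- matrix(0, 8, 2, dimnames = dimnames(Y))
  model <- structure(list(C = C, Sigma = S, traits = c("t1", "t2"),
                          loglik = NA), class = "mtlmm_model")
  tr <- ids[1:6]; te <- ids[7:8]

  # dense 16x16 oracle: observed = train both traits + test's other trait
  pr <- predict_mtlmm(model, K, Fm, Y, tr, te, "t1",
                      include_residual = FALSE)
  obs <- c(1:6, 9:16); unk <- 7:8
  orc <- mvn_condition_oracle(rep(0, 16), V, obs, unk, y_vec[obs])
  expect_equal(pr$pred_mean, orc$mean, tolerance = 1e-8)
  expect_equal(sqrt(pr$pred_sd^2 + S["t1", "t1"]), orc$sd, tolerance = 1e-8)

  # diagonal C and Sigma: equals the independent single-trait BLUP
  Cd <- diag(diag(C)); Sd <- diag(diag(S))
  dimnames(Cd) <- dimnames(Sd) <- dimnames(C)
  model_d <- structure(list(C = Cd, Sigma = Sd, traits = c("t1", "t2"),
                            loglik = NA), class = "mtlmm_model")
  pr_d <- predict_mtlmm(model_d, K, Fm, Y, tr, te, "t1")
  vc1 <- structure(list(sigma_g2 = Cd[1, 1], sigma_e2 = Sd[1, 1], mu = 0,
                        h2 = NA), class = "varcomp")
  bp <- blup_predict(K, Y[tr, "t1"], tr, te, vc = vc1)
  expect_equal(pr_d$pred_mean, bp$pred_mean, tolerance = 1e-8)
  expect_equal(pr_d$pred_sd, bp$pred_sd, tolerance = 1e-8)
})

test_that("multi-trait ML fitting recovers covariance structure", {
  set.seed(55)
  n <- 120
  Z <- matrix(rnorm(n * 80), n, 80)
  K <- tcrossprod(Z) / mean(diag(tcrossprod(Z)))
  ids <- paste0("i", 1:n); dimnames(K) <- list(ids, ids)
  C <- matrix(c(1, 0.7, 0.7, 1), 2); S <- diag(0.3, 2)
  V <- kronecker(C, K) + kronecker(S, diag(n))
  Y <- matrix(as.vector(crossprod(chol(V), rnorm(2 * n))), n, 2,
              dimnames = list(ids, c("t1", "t2")))
  Fm <- matrix(0, n, 2, dimnames = dimnames(Y))
  fit <- fit_mtlmm(Y, Fm, K, maxit = 300)
  # genetic correlation recovered with a generous margin
  gcor <- fit$C[1, 2] / sqrt(fit$C[1, 1] * fit$C[2, 2])
  expect_gt(gcor, 0.4)
  expect_lt(abs(fit$C[1, 1] - 1), 0.6)
})
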