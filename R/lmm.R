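# Linear mixed models combining QTL fixed effects with the genomic
# relatedness random effect; the phenotype-augmented LMM+P variant; and the
# midparent predictor.

#' Fit a linear mixed model: QTL fixed effects plus genomic relatedness
#'
#' Fixed effects (additive QTLs plus dominance/interaction terms) are built by
#' [fit_qtl_model()] on the training data only; the genetic random component
#' is then fit on the fixed-effect residuals: variance components of
#' `N(mu * 1, sigma_g2 * K + sigma_e2 * I)` by maximum likelihood, and
#' prediction adds the conditional (BLUP) genetic mean for test individuals to
#' the fixed-effect prediction. With no fixed terms the model reduces exactly
#' to [blup_predict()]; with `sigma_g2 = 0` it reduces to OLS on the fixed
#' effects.
#'
#' @param G Full dosage matrix (train and test rows).
#' @param K A `grm` over at least the training and test individuals.
#' @param y_train Training phenotypes in `train_ids` order.
#' @param train_ids Training individual ids.
#' @param fixed Optional pre-fitted `qtl_model` to use as fixed effects;
#'   fitted here when `NULL`.
#' @param interactions Include the dominance/interaction stage when fitting
#'   fixed effects (default `TRUE`; this is what distinguishes the LMM from
#'   BLUP + additive QTLs).
#' @param max_terms,max_int_terms,n_folds,seed Passed to [fit_qtl_model()].
#' @return An object of class `lmm_model` with the `fixed` QTL model, the
#'   residual `vc` (class `varcomp`), and training bookkeeping.
#' @export
fit_lmm <- function(G, K, y_train, train_ids, fixed = NULL,
                    interactions = TRUE, max_terms = 50, max_int_terms = 20,
                    n_folds = 4, seed = 1) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  if (is.null(fixed)) {
    fixed <- fit_qtl_model(G[train_ids, , drop = FALSE], y_train,
                           max_terms = max_terms, interactions = interactions,
                           max_int_terms = max_int_terms, n_folds = n_folds,
                           seed = seed)
  }
  # fixed-effect contribution without the intercept; the mixed model's GLS
  # mean absorbs it, so the no-terms case reduces exactly to BLUP
  fx_train <- if (fixed$n_terms > 0) {
    as.vector(term_columns(G[train_ids, , drop = FALSE], fixed$terms) %*%
                fixed$coef[-1])
  } else rep(0, length(y_train))
  resid_tr <- y_train - fx_train
  vc <- fit_variance_components(Km[train_ids, train_ids], resid_tr)
  structure(list(fixed = fixed, vc = vc, K = Km, train_ids = train_ids,
                 resid_train = resid_tr),
            class = "lmm_model")
}

#' @export
predict.lmm_model <- function(object, G_new, test_ids, ...) {
  fx <- if (object$fixed$n_terms > 0) {
    as.vector(term_columns(G_new[test_ids, , drop = FALSE],
                           object$fixed$terms) %*% object$fixed$coef[-1])
  } else rep(0, length(test_ids))
  bp <- blup_predict(object$K, object$resid_train, object$train_ids, test_ids,
                     vc = object$vc)
  out <- tibble(hybrid_id = test_ids,
                pred_mean = fx + bp$pred_mean,
                pred_sd = bp$pred_sd)
  attr(out, "mean_sd") <- sqrt(mean(out$pred_sd^2))
  class(out) <- c("predictive_dist", class(out))
  out
}

#' @export
glance.lmm_model <- function(x, ...) {
  tibble(n_terms = x$fixed$n_terms, sigma_g2 = x$vc$sigma_g2,
         sigma_e2 = x$vc$sigma_e2, h2_resid = x$vc$h2)
}

#' Fit the phenotype-augmented LMM (LMM+P)
#'
#' Two-stage composite: first `y` is regressed on the other measured traits
#' `P` ([fit_phenotype_regression()]); the LMM of [fit_lmm()] is then fit on
#' the stage-1 residuals. Prediction for a test individual uses its observed
#' other traits for stage 1 plus the genetic stage-2 prediction.
#'
#' @param P_train Covariate-trait matrix for training individuals.
#' @param y_train Training response.
#' @param G,K,train_ids,... As in [fit_lmm()].
#' @return An object of class `lmm_p_model`.
#' @export
fit_lmm_plus_p <- function(P_train, y_train, G, K, train_ids, ...) {
  stage1 <- fit_phenotype_regression(P_train, y_train)
  resid1 <- y_train - predict(stage1, P_train)
  stage2 <- fit_lmm(G, K, resid1, train_ids, ...)
  structure(list(stage1 = stage1, stage2 = stage2), class = "lmm_p_model")
}

#' @export
predict.lmm_p_model <- function(object, G_new, P_new, test_ids, ...) {
  p1 <- unname(predict(object$stage1, P_new))
  p2 <- predict(object$stage2, G_new, test_ids)
  out <- tibble(hybrid_id = test_ids,
                pred_mean = p1 + p2$pred_mean,
                pred_sd = p2$pred_sd)
  attr(out, "mean_sd") <- sqrt(mean(out$pred_sd^2))
  class(out) <- c("predictive_dist", class(out))
  out
}

#' Fit the midparent model on a training diallel
#'
#' Least-squares fit of the additive two-way layout
#' `y_ij = (P1_i + P2_j) / 2` over the training hybrids, i.e. an OLS fit of
#' `y ~ parent_a + parent_alpha` as factors; the fitted parental values are
#' stored so that the prediction for hybrid `(i, j)` is exactly the midparent
#' value `(P1_i + P2_j) / 2`.
#'
#' @param ped Pedigree tibble covering the training hybrids.
#' @param y_train Training phenotypes, in `train_ids` order.
#' @param train_ids Training hybrid ids.
#' @return An object of class `midparent_model` with tibbles
#'   `parents_a`/`parents_alpha` of fitted parental values.
#' @export
fit_midparent <- function(ped, y_train, train_ids = ped$hybrid_id) {
  d <- ped[match(train_ids, ped$hybrid_id), ]
  if (anyNA(d$hybrid_id)) abort_arg("training ids missing from pedigree")
  a_lev <- sort(unique(d$parent_a)); b_lev <- sort(unique(d$parent_alpha))
  # full indicator design for the additive two-way layout (no reference
  # level); the intercept confounding is resolved by the minimum-norm
  # least-squares solution, which leaves predictions a_i + b_j unchanged
  X <- cbind(outer(d$parent_a, a_lev, `==`) + 0,
             outer(d$parent_alpha, b_lev, `==`) + 0)
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  coefs <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], y_train) / sv$d[pos])
  a_eff <- coefs[seq_along(a_lev)]
  b_eff <- coefs[length(a_lev) + seq_along(b_lev)]
  # parameterize so that prediction (P1_i + P2_j)/2 = a_i + b_j
  structure(list(
    parents_a = tibble(parent = a_lev, value = 2 * as.vector(a_eff)),
    parents_alpha = tibble(parent = b_lev, value = 2 * as.vector(b_eff))),
    class = "midparent_model")
}

#' Predict hybrids from a fitted midparent model
#'
#' @param model A `midparent_model`.
#' @param ped Pedigree tibble.
#' @param test_ids Hybrid ids to predict.
#' @return A tibble `(hybrid_id, pred_mean)`; hybrids with a parent unseen in
#'   training get `NA` with a warning.
#' @export
predict_midparent <- function(model, ped, test_ids) {
  d <- ped[match(test_ids, ped$hybrid_id), ]
  if (anyNA(d$hybrid_id)) abort_arg("test ids missing from pedigree")
  p1 <- model$parents_a$value[match(d$parent_a, model$parents_a$parent)]
  p2 <- model$parents_alpha$value[match(d$parent_alpha, model$parents_alpha$parent)]
  pred <- (p1 + p2) / 2
  if (anyNA(pred)) {
    warn(sprintf("%d test hybrids have a parent unseen in training; predictions are NA",
                 sum(is.na(pred))))
  }
  tibble(hybrid_id = test_ids, pred_mean = pred)
}

#' @export
predict.midparent_model <- function(object, ped, test_ids, ...) {
  predict_midparent(object, ped, test_ids)
}

#' @export
tidy.midparent_model <- function(x, ...) {
  bind_rows(mutate(x$parents_a, panel = "MatA"),
            mutate(x$parents_alpha, panel = "MatAlpha"))
}
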