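# Baseline predictors: regression on other phenotypes, genomic BLUP with
# model-derived predictive uncertainty, and heritability/repeatability
# estimators.

#' Regress a trait on the other measured phenotypes
#'
#' Ordinary least squares of `y` on the covariate traits plus an intercept.
#' Rank-deficient covariate matrices are solved by the minimum-norm solution
#' (SVD pseudoinverse) with a warning.
#'
#' @param P_train Covariate matrix or data frame (individuals x traits).
#' @param y_train Response vector.
#' @return An object of class `phenreg` with `beta`, `intercept`, training
#'   residual variance `sigma2` and column names.
#' @export
fit_phenotype_regression <- function(P_train, y_train) {
  P <- as.matrix(P_train)
  if (anyNA(P) || anyNA(y_train)) abort_arg("missing values are not allowed")
  if (nrow(P) != length(y_train)) abort_arg("rows(P_train) must equal length(y_train)")
  X <- cbind(`(Intercept)` = 1, P)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < ncol(X)) {
    warn("rank-deficient covariate matrix; using the minimum-norm solution")
  }
  coefs <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y_train)) / sv$d[pos])
  fit <- as.vector(X %*% coefs)
  df <- max(length(y_train) - sum(pos), 1)
  structure(list(beta = setNames(coefs[-1], colnames(P)),
                 intercept = coefs[1],
                 sigma2 = sum((y_train - fit)^2) / df,
                 terms = colnames(P)),
            class = "phenreg")
}

#' @export
predict.phenreg <- function(object, newdata, ...) {
  P <- as.matrix(newdata)[, object$terms, drop = FALSE]
  if (anyNA(P)) abort_arg("missing covariate traits for some individuals; no imputation is performed")
  as.vector(object$intercept + P %*% object$beta)
}

#' @export
tidy.phenreg <- function(x, ...) {
  tibble(term = c("(Intercept)", x$terms),
         estimate = c(x$intercept, unname(x$beta)))
}

#' Fit variance components of the genomic BLUP model
#'
#' Maximum-likelihood fit of `y ~ N(mu * 1, sigma_g2 * K + sigma_e2 * I)` via
#' one eigendecomposition of `K` and a 1-D search over the log variance ratio
#' `delta = sigma_e2 / sigma_g2` (Brent on `log(delta)` over
#' `[log 1e-6, log 1e6]`, tolerance 1e-8), with the mean and the overall scale
#' profiled out in closed form at each ratio. Narrow-sense heritability is
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` (`K` has mean diagonal 1, so
#' `sigma_g2` is on the phenotypic scale).
#'
#' @param K A `grm` object or a PSD matrix.
#' @param y Phenotype vector (typically replicate means), same order as `K`.
#' @return An object of class `varcomp`: `sigma_g2`, `sigma_e2`, `mu`, `h2`,
#'   `loglik`.
#' @export
fit_variance_components <- function(K, y) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  n <- length(y)
  if (nrow(Km) != n) abort_arg("dim(K) must match length(y)")
  if (anyNA(y)) abort_arg("missing phenotypes are not allowed")
  if (var(y) < .Machine$double.eps) {
    warn("constant phenotype; returning sigma_g2 = 0")
    return(structure(list(sigma_g2 = 0, sigma_e2 = 0, mu = y[1], h2 = 0,
                          loglik = NA_real_), class = "varcomp"))
  }
  eig <- eigen(Km, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yt <- as.vector(crossprod(eig$vectors, y))
  ot <- as.vector(crossprod(eig$vectors, rep(1, n)))
  nll <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    mu <- sum(w * ot * yt) / sum(w * ot^2)
    res <- yt - mu * ot
    sg <- sum(w * res^2) / n
    0.5 * (n * log(2 * pi) + n * log(sg) + sum(log(d + delta)) + n)
  }
  opt <- optimize(nll, c(log(1e-6), log(1e6)), tol = 1e-8)
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  mu <- sum(w * ot * yt) / sum(w * ot^2)
  sg <- sum(w * (yt - mu * ot)^2) / n
  structure(list(sigma_g2 = sg, sigma_e2 = sg * delta, mu = mu,
                 h2 = 1 / (1 + delta), loglik = -opt$objective),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("<varcomp: sigma_g2 = %.4g, sigma_e2 = %.4g, mu = %.4g, h2 = %.3f>\n",
              x$sigma_g2, x$sigma_e2, x$mu, x$h2))
  invisible(x)
}

#' @export
tidy.varcomp <- function(x, ...) {
  tibble(component = c("sigma_g2", "sigma_e2", "mu"),
         estimate = c(x$sigma_g2, x$sigma_e2, x$mu))
}

#' @export
glance.varcomp <- function(x, ...) {
  tibble(h2 = x$h2, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
         mu = x$mu, logLik = x$loglik)
}

#' Estimate narrow-sense heritability from the genomic BLUP model
#'
#' Fits the BLUP variance components and reports
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`. When given a dosage matrix, the
#' relatedness matrix is built from *centred* dosages: on the uncentred
#' `X X^T / c`, most of the diagonal is the squared allele-dosage mean rather
#' than genetic variance, which leaves `sigma_g2` off the phenotypic scale and
#' inflates the ratio; centring restores the standard scale on which the
#' heritability interpretation rests. (Prediction itself is insensitive to
#' this choice because of the fitted mean.)
#'
#' @param x A dosage matrix (preferred; centred GRM is built internally) or a
#'   pre-built `grm`/matrix used as-is.
#' @param y Phenotype vector (replicate means), in row order of `x`.
#' @return The ML estimate of `h2`.
#' @export
estimate_h2 <- function(x, y) {
  K <- if (inherits(x, "grm") || (is.matrix(x) && nrow(x) == ncol(x) &&
                                  !all(x %in% 0:2))) {
    x
  } else {
    compute_grm(x, center = TRUE)
  }
  fit_variance_components(K, y)$h2
}

# Cholesky, falling back to an escalating jitter; errors if persistently
# singular
chol_jitter <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) return(R)
  jit <- 1e-8 * mean(diag(S))
  for (k in 0:4) {
    R <- tryCatch(chol(S + diag(jit * 10^k, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  abort("training covariance is numerically singular even after jitter",
        class = "dgp_numerical_error")
}

#' Genomic BLUP prediction with predictive uncertainty
#'
#' Conditions the multivariate normal model
#' `y ~ N(mu * 1, sigma_g2 * K + sigma_e2 * I)` on the training phenotypes to
#' obtain, for each test individual, the conditional mean and variance of its
#' genetic value. By default the reported predictive standard deviation is for
#' a *measured* phenotype, i.e. `sqrt(conditional genetic variance +
#' sigma_e2)`; set `include_residual = FALSE` for the genetic-value SD only.
#'
#' @param K A `grm` object or matrix covering train and test individuals.
#' @param y_train Training phenotypes, in `train_ids` order.
#' @param train_ids,test_ids Disjoint id vectors (or integer indices into `K`).
#' @param vc A `varcomp` fitted on the training data; fitted here if `NULL`.
#' @param include_residual Include `sigma_e2` in the predictive variance.
#' @return A tibble of class `predictive_dist` with columns `hybrid_id`,
#'   `pred_mean`, `pred_sd`; attribute `mean_sd` is the square root of the
#'   average predictive variance.
#' @export
blup_predict <- function(K, y_train, train_ids, test_ids, vc = NULL,
                         include_residual = TRUE) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  if (length(intersect(train_ids, test_ids)) > 0) {
    abort_arg("train and test sets must be disjoint")
  }
  if (is.null(vc)) vc <- fit_variance_components(Km[train_ids, train_ids], y_train)
  sg <- vc$sigma_g2; se <- vc$sigma_e2; mu <- vc$mu
  Ktr <- Km[train_ids, train_ids, drop = FALSE]
  Kte_tr <- Km[test_ids, train_ids, drop = FALSE]
  if (sg <= 0) {
    pm <- rep(mu, length(test_ids))
    pv <- rep(0, length(test_ids))
  } else {
    S_tr <- sg * Ktr + diag(se, length(train_ids))
    R <- chol_jitter(S_tr)
    alpha <- backsolve(R, backsolve(R, y_train - mu, transpose = TRUE))
    Cte <- sg * Kte_tr
    pm <- mu + as.vector(Cte %*% alpha)
    W <- backsolve(R, t(Cte), transpose = TRUE)  # R^-T Cte^T
    pv <- pmax(sg * diag(Km)[test_ids] - colSums(W^2), 0)
  }
  sd2 <- unname(pv) + if (include_residual) se else 0
  out <- tibble(hybrid_id = if (is.character(test_ids)) test_ids else
                  (rownames(Km)[test_ids] %||% as.character(test_ids)),
                pred_mean = unname(pm), pred_sd = sqrt(sd2))
  attr(out, "mean_sd") <- sqrt(mean(sd2))
  attr(out, "vc") <- vc
  class(out) <- c("predictive_dist", class(out))
  out
}

#' Estimate repeatability from replicate measurements
#'
#' Fits the fixed-effects model `r_ij = y_i + eps_ij` with `y_i` the
#' individual mean, and estimates repeatability of a single measurement as
#' `1 - sigma^2 / Var(r)`, where the variance components come from the
#' unbiased one-way ANOVA decomposition: `sigma^2` is the within-individual
#' mean square and `Var(r) = sigma_b^2 + sigma^2` the total variance, with the
#' between-individual component `sigma_b^2 = (MS_between - MS_within) / n_rep`
#' (truncated at zero). The repeatability of the `n_rep`-average is
#' `sigma_b^2 / (sigma_b^2 + sigma^2 / n_rep)`.
#'
#' @param pheno Long phenotype tibble `(hybrid_id, trait, replicate, value)`.
#' @param trait Trait name to estimate for.
#' @return A named list `(H2_mean, H2_single)`.
#' @export
estimate_repeatability <- function(pheno, trait) {
  d <- pheno[pheno$trait == trait, ]
  if (nrow(d) == 0) abort_arg(sprintf("unknown trait: %s", trait))
  counts <- table(d$hybrid_id)
  if (any(counts < 2)) abort_arg("repeatability needs >= 2 replicates per individual")
  n_ind <- length(counts)
  n_tot <- nrow(d)
  n_rep <- n_tot / n_ind
  mu_i <- ave(d$value, d$hybrid_id)
  ss_within <- sum((d$value - mu_i)^2)
  ss_between <- sum((mu_i - mean(d$value))^2)
  sigma2 <- ss_within / (n_tot - n_ind)
  ms_between <- if (n_ind > 1) ss_between / (n_ind - 1) else 0
  if (ss_within == 0 && ss_between == 0) {
    return(list(H2_mean = 1, H2_single = 1))
  }
  if (sigma2 == 0) return(list(H2_mean = 1, H2_single = 1))
  sigma_b2 <- max((ms_between - sigma2) / n_rep, 0)
  list(H2_mean = sigma_b2 / (sigma_b2 + sigma2 / n_rep),
       H2_single = sigma_b2 / (sigma_b2 + sigma2))
}
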