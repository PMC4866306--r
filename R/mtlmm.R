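# Multi-trait linear mixed model: joint covariance C (x) K + Sigma (x) I over
# individuals x traits, with per-trait fixed effects taken from the
# single-trait models.

# lower-triangular Cholesky factor from a parameter vector (log-diagonal)
par_to_chol <- function(par, T) {
  L <- matrix(0, T, T)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  L
}

chol_to_par <- function(L) {
  M <- L
  diag(M) <- log(pmax(diag(M), 1e-6))
  M[lower.tri(M, diag = TRUE)]
}

#' Fit a multi-trait LMM by maximum likelihood
#'
#' Models the matrix of fixed-effect residuals `R = Y - F` (individuals x
#' traits) as matrix-variate normal with covariance `C (x) K + Sigma (x) I`,
#' where `C` is the genetic trait-by-trait covariance and `Sigma` the
#' non-genetic one. After rotating by the eigenvectors of `K`, rows are
#' independent with covariance `d_i * C + Sigma`, and the likelihood is
#' maximized by quasi-Newton optimization over Cholesky factors of `C` and
#' `Sigma` (positive semi-definite by construction), initialized from
#' single-trait variance-component fits.
#'
#' @param Y Phenotype matrix (training individuals x traits, replicate means).
#' @param F Fixed-effect predictions per trait, same shape as `Y` (e.g. each
#'   trait's QTL-model predictions); zero matrix for a pure random-effect fit.
#' @param K A `grm` or PSD matrix over the training individuals.
#' @param maxit Optimizer iteration cap.
#' @return An object of class `mtlmm_model` with `C`, `Sigma`, `traits` and
#'   the achieved `loglik`.
#' @export
fit_mtlmm <- function(Y, F, K, maxit = 200) {
  Y <- as.matrix(Y); F <- as.matrix(F)
  stopifnot(identical(dim(Y), dim(F)))
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  n <- nrow(Y); T <- ncol(Y)
  if (T < 2) abort_arg("the multi-trait model needs >= 2 traits")
  R <- Y - F
  eig <- eigen(Km, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  Rt <- crossprod(eig$vectors, R)
  nll <- function(par) {
    half <- length(par) / 2
    LC <- par_to_chol(par[seq_len(half)], T)
    LS <- par_to_chol(par[-seq_len(half)], T)
    C <- tcrossprod(LC); S <- tcrossprod(LS)
    val <- 0
    for (i in seq_len(n)) {
      V <- d[i] * C + S
      cf <- tryCatch(chol(V + diag(1e-10, T)), error = function(e) NULL)
      if (is.null(cf)) return(1e10)
      z <- backsolve(cf, Rt[i, ], transpose = TRUE)
      val <- val + 2 * sum(log(diag(cf))) + sum(z^2)
    }
    0.5 * (val + n * T * log(2 * pi))
  }
  # initialize from single-trait fits; zero genetic cross-covariance
  init_C <- diag(T); init_S <- diag(T)
  for (t in seq_len(T)) {
    vc <- fit_variance_components(Km, R[, t])
    init_C[t, t] <- max(vc$sigma_g2, 1e-4)
    init_S[t, t] <- max(vc$sigma_e2, 1e-4)
  }
  par0 <- c(chol_to_par(chol_default(init_C)), chol_to_par(chol_default(init_S)))
  opt <- optim(par0, nll, method = "BFGS", control = list(maxit = maxit))
  half <- length(opt$par) / 2
  C <- tcrossprod(par_to_chol(opt$par[seq_len(half)], T))
  S <- tcrossprod(par_to_chol(opt$par[-seq_len(half)], T))
  dimnames(C) <- dimnames(S) <- list(colnames(Y), colnames(Y))
  structure(list(C = C, Sigma = S, traits = colnames(Y),
                 loglik = -opt$value, convergence = opt$convergence),
            class = "mtlmm_model")
}

chol_default <- function(M) t(chol(M))

#' @export
print.mtlmm_model <- function(x, ...) {
  cat(sprintf("<mtlmm_model: %d traits, logLik = %.3f>\n",
              length(x$traits), x$loglik))
  invisible(x)
}

#' @export
glance.mtlmm_model <- function(x, ...) {
  tibble(n_traits = length(x$traits), logLik = x$loglik,
         convergence = x$convergence)
}

#' Predict a focal trait with a fitted multi-trait LMM
#'
#' Conditions the joint multivariate normal over all (individual, trait) cells
#' — training individuals' phenotypes for every trait, plus the test
#' individuals' *other* traits — to obtain the predictive distribution of the
#' test individuals' focal trait. This is the multi-trait analogue of the
#' phenotype-augmented single-trait model.
#'
#' @param model A fitted `mtlmm_model`.
#' @param K A `grm` or matrix over training and test individuals.
#' @param F_all Fixed-effect predictions, (all individuals) x traits, rows
#'   named by individual id.
#' @param Y_all Observed phenotype matrix with the same shape as `F_all`; the
#'   test individuals' focal-trait entries are ignored.
#' @param train_ids,test_ids Disjoint id vectors.
#' @param trait Focal trait name.
#' @param include_residual Include the non-genetic variance of the focal trait
#'   in the predictive SD.
#' @return A `predictive_dist` tibble (`hybrid_id`, `pred_mean`, `pred_sd`).
#' @export
predict_mtlmm <- function(model, K, F_all, Y_all, train_ids, test_ids, trait,
                          include_residual = TRUE) {
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  traits <- model$traits
  if (!trait %in% traits) abort_arg(sprintf("unknown focal trait: %s", trait))
  ids <- c(train_ids, test_ids)
  Ksub <- Km[ids, ids, drop = FALSE]
  n <- length(ids); T <- length(traits)
  F_all <- as.matrix(F_all)[ids, traits, drop = FALSE]
  Y_all <- as.matrix(Y_all)[ids, traits, drop = FALSE]
  # cells stacked trait-major: cell index = (t-1)*n + i
  V <- kronecker(model$C, Ksub) + kronecker(model$Sigma, diag(n))
  mu <- as.vector(F_all)
  obs_mask <- matrix(TRUE, n, T)
  te_rows <- (length(train_ids) + 1):n
  obs_mask[te_rows, match(trait, traits)] <- FALSE
  obs <- as.vector(obs_mask)
  y_vec <- as.vector(Y_all)
  V_oo <- V[obs, obs, drop = FALSE]
  V_uo <- V[!obs, obs, drop = FALSE]
  R <- chol_jitter(V_oo)
  alpha <- backsolve(R, backsolve(R, y_vec[obs] - mu[obs], transpose = TRUE))
  pm <- mu[!obs] + as.vector(V_uo %*% alpha)
  W <- backsolve(R, t(V_uo), transpose = TRUE)
  pv <- pmax(diag(V)[!obs] - colSums(W^2), 0)
  # diag(V) at the unknown cells already contains Sigma[trait, trait]; strip
  # it when the genetic-value SD is requested
  if (!include_residual) {
    pv <- pmax(pv - model$Sigma[trait, trait], 0)
  }
  out <- tibble(hybrid_id = test_ids, pred_mean = pm, pred_sd = sqrt(pv))
  attr(out, "mean_sd") <- sqrt(mean(pv))
  class(out) <- c("predictive_dist", class(out))
  out
}
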