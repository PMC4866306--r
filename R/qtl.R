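# Forward-selection QTL models with nested (double) cross-validation sizing.
#
# Terms are encoded as strings: a bare site id is an additive term; "a:b" is
# the elementwise product of the dosage columns of sites a and b (an epistatic
# interaction), and the self-pair "a:a" the squared dosage column, which
# captures dominance.

# design columns for a vector of term strings
term_columns <- function(G, terms) {
  if (length(terms) == 0) {
    return(matrix(0, nrow(G), 0, dimnames = list(rownames(G), character())))
  }
  cols <- vapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    bad <- setdiff(parts, colnames(G))
    if (length(bad)) abort_arg(sprintf("unknown site in term `%s`", tm))
    if (length(parts) == 1) as.numeric(G[, parts]) else
      as.numeric(G[, parts[1]]) * as.numeric(G[, parts[2]])
  }, numeric(nrow(G)))
  colnames(cols) <- terms
  cols
}

#' Greedy forward selection of regression terms
#'
#' At each step adds the candidate column that most reduces the residual sum
#' of squares of the OLS fit containing the intercept, all `include` columns
#' and all previously selected terms. Ties are broken by the lowest column
#' index. Candidates that become numerically collinear with the current model
#' are skipped; selection stops early when no usable candidate remains.
#'
#' @param X Candidate design matrix (columns named by term).
#' @param y Response vector.
#' @param max_terms Maximum number of terms to select (the QTL models cap the
#'   additive stage at 50).
#' @param include Optional matrix of columns kept in the model throughout.
#' @return A tibble `(step, term, rss)` recording the greedy path.
#' @export
forward_select_terms <- function(X, y, max_terms = 50, include = NULL) {
  if (is.null(dim(X)) || ncol(X) == 0) abort_arg("no candidate terms")
  assert_scalar_count(max_terms, "max_terms")
  n <- nrow(X)
  q <- rep(1 / sqrt(n), n)
  r <- y - q * sum(q * y)
  Xo <- X - outer(q, as.vector(crossprod(X, q)))
  if (!is.null(include) && ncol(include) > 0) {
    Inc <- include - outer(q, as.vector(crossprod(include, q)))
    for (k in seq_len(ncol(Inc))) {
      v <- Inc[, k]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-10) next
      qk <- v / nv
      r <- r - qk * sum(qk * r)
      Xo <- Xo - outer(qk, as.vector(crossprod(Xo, qk)))
      if (k < ncol(Inc)) {
        Inc[, (k + 1):ncol(Inc)] <- Inc[, (k + 1):ncol(Inc), drop = FALSE] -
          outer(qk, as.vector(crossprod(Inc[, (k + 1):ncol(Inc), drop = FALSE], qk)))
      }
    }
  }
  avail <- rep(TRUE, ncol(X))
  sel <- integer(0); rss <- numeric(0)
  for (step in seq_len(min(max_terms, ncol(X)))) {
    ss <- colSums(Xo^2)
    num <- as.vector(crossprod(Xo, r))
    red <- ifelse(avail & ss > 1e-10 * n, num^2 / ss, -Inf)
    if (!any(is.finite(red))) break
    j <- which.max(red)
    qk <- Xo[, j] / sqrt(ss[j])
    r <- r - qk * sum(qk * r)
    Xo <- Xo - outer(qk, as.vector(crossprod(Xo, qk)))
    avail[j] <- FALSE
    sel <- c(sel, j)
    rss <- c(rss, sum(r^2))
  }
  tibble(step = seq_along(sel),
         term = colnames(X)[sel],
         rss = rss)
}

# predictions of all prefix models (0..T terms, with intercept) on a test set,
# via Gram-Schmidt on the training design mirrored onto the test columns
prefix_predictions <- function(Xtr, ytr, Xte) {
  A <- cbind(1, Xtr); B <- cbind(1, Xte)
  Tn <- ncol(A)
  preds <- matrix(NA_real_, nrow(B), Tn)
  cur <- rep(0, nrow(B))
  for (k in seq_len(Tn)) {
    v <- A[, k]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      qk <- v / nv
      bk <- B[, k] / nv
      cur <- cur + sum(qk * ytr) * bk
      if (k < Tn) {
        proj <- as.vector(crossprod(A[, (k + 1):Tn, drop = FALSE], qk))
        A[, (k + 1):Tn] <- A[, (k + 1):Tn, drop = FALSE] - outer(qk, proj)
        B[, (k + 1):Tn] <- B[, (k + 1):Tn, drop = FALSE] - outer(bk, proj)
      }
    }
    preds[, k] <- cur
  }
  preds  # column t+1 = prediction with t terms
}

# inner-CV R^2 of every prefix model along an ordered term path
path_cv_r2 <- function(Xpath, y, n_folds = 4, seed = 1) {
  n <- length(y)
  if (n_folds > n) abort_arg("more inner folds than training individuals")
  folds <- with_seed(derive_seed(seed, "inner-cv"),
                     sample(rep(seq_len(n_folds), length.out = n)))
  r2 <- matrix(NA_real_, n_folds, ncol(Xpath) + 1)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    preds <- prefix_predictions(Xpath[!te, , drop = FALSE], y[!te],
                                Xpath[te, , drop = FALSE])
    r2[f, ] <- apply(preds, 2, function(p) r2_score(y[te], p))
  }
  r2
}

#' Choose the model size along a forward-selection path by inner CV
#'
#' Given the ordered term path from [forward_select_terms()] on the training
#' data, evaluates every prefix model (including the empty, intercept-only
#' model) by `n_folds`-fold cross-validation *within* the training set and
#' returns the size maximizing the mean out-of-fold `R^2` (smallest size on
#' ties), with weights refit on all training data. Together with an outer
#' evaluation loop this is a double cross-validation scheme.
#'
#' @param X Design columns for the path terms, in path order (training rows).
#' @param y Training response.
#' @param path Character vector of term names in selection order (defaults to
#'   `colnames(X)`).
#' @param n_folds Inner folds (default 4).
#' @param seed Integer seed for the inner fold assignment.
#' @return An object of class `qtl_model`: selected `terms`, `coef`
#'   (including `(Intercept)`), `n_terms`, `sigma2`, the inner-CV curve
#'   `cv` (`size`, `mean_r2`), and `XtX_inv` for predictive variances.
#' @export
select_model_size <- function(X, y, path = colnames(X), n_folds = 4, seed = 1) {
  X <- X[, path, drop = FALSE]
  r2 <- path_cv_r2(X, y, n_folds = n_folds, seed = seed)
  curve <- colMeans(r2, na.rm = TRUE)
  t_star <- if (!any(is.finite(curve))) 0L else
    which.max(replace(curve, !is.finite(curve), -Inf)) - 1L
  fit_qtl_weights(X[, seq_len(t_star), drop = FALSE], y,
                  cv = tibble(size = seq_along(curve) - 1L, mean_r2 = curve))
}

# OLS refit of a fixed term set, packaged as a qtl_model
fit_qtl_weights <- function(X, y, cv = NULL) {
  A <- cbind(`(Intercept)` = 1, X)
  qra <- qr(A)
  beta <- qr.coef(qra, y)
  beta[is.na(beta)] <- 0
  res <- y - as.vector(A %*% beta)
  df <- max(length(y) - qra$rank, 1)
  XtX_inv <- tryCatch(solve(crossprod(A)), error = function(e) NULL)
  structure(list(terms = colnames(X), coef = beta,
                 n_terms = ncol(X), sigma2 = sum(res^2) / df,
                 cv = cv, XtX_inv = XtX_inv),
            class = "qtl_model")
}

#' Expand interaction and dominance candidates from selected additive terms
#'
#' All pairs `(i, j)` where `i` has previously been selected as an additive
#' term and `j` is any site, encoded as elementwise products of dosage
#' columns; self-pairs `(i, i)` give the squared dosage column and capture
#' dominance. Unordered duplicates are removed.
#'
#' @param selected Character vector of selected additive site ids.
#' @param sites All candidate site ids.
#' @return Character vector of interaction terms `"a:b"`.
#' @export
expand_interaction_candidates <- function(selected, sites) {
  if (length(selected) == 0) abort_arg("at least one additive term must be selected")
  pairs <- expand_grid(i = selected, j = sites) |>
    mutate(a = pmin(.data$i, .data$j), b = pmax(.data$i, .data$j)) |>
    distinct(.data$a, .data$b)
  paste0(pairs$a, ":", pairs$b)
}

#' Fit a forward-selection QTL model with double-CV model sizing
#'
#' Runs greedy forward selection over additive site terms (up to `max_terms`
#' iterations), sizes the model by inner cross-validation, and, if
#' `interactions = TRUE`, expands dominance/epistasis candidates from the
#' selected additive terms, continues forward selection over them, and
#' re-sizes the combined path by inner cross-validation.
#'
#' @param G Training dosage matrix.
#' @param y Training response (replicate means).
#' @param max_terms Cap on additive forward-selection iterations (default 50).
#' @param interactions Add interaction/dominance stage.
#' @param max_int_terms Cap on interaction-stage iterations.
#' @param n_folds Inner CV folds.
#' @param seed Integer seed (inner fold assignment).
#' @return A `qtl_model`.
#' @export
fit_qtl_model <- function(G, y, max_terms = 50, interactions = FALSE,
                          max_int_terms = 20, n_folds = 4, seed = 1) {
  X <- G
  storage.mode(X) <- "double"
  path <- forward_select_terms(X, y, max_terms = max_terms)
  if (nrow(path) == 0) return(fit_qtl_weights(X[, 0, drop = FALSE], y))
  Xpath <- X[, path$term, drop = FALSE]
  m_add <- select_model_size(Xpath, y, n_folds = n_folds, seed = seed)
  if (!interactions || m_add$n_terms == 0) return(m_add)
  add_terms <- m_add$terms
  cand <- expand_interaction_candidates(add_terms, colnames(G))
  Xadd <- X[, add_terms, drop = FALSE]
  Xint <- term_columns(G, cand)
  ipath <- forward_select_terms(Xint, y, max_terms = max_int_terms,
                                include = Xadd)
  Xfull <- cbind(Xadd, Xint[, ipath$term, drop = FALSE])
  select_model_size(Xfull, y, n_folds = n_folds,
                    seed = derive_seed(seed, "int-stage"))
}

#' @export
predict.qtl_model <- function(object, G_new, se = FALSE, ...) {
  X <- term_columns(G_new, object$terms)
  A <- cbind(1, X)
  pred <- as.vector(A %*% object$coef)
  if (!se) return(pred)
  pv <- if (is.null(object$XtX_inv)) rep(NA_real_, nrow(A)) else
    object$sigma2 * (1 + rowSums((A %*% object$XtX_inv) * A))
  tibble(pred_mean = pred, pred_sd = sqrt(pmax(pv, 0)))
}

#' @export
tidy.qtl_model <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.qtl_model <- function(x, ...) {
  tibble(n_terms = x$n_terms, sigma2 = x$sigma2,
         cv_r2 = if (is.null(x$cv)) NA_real_ else max(x$cv$mean_r2))
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("<qtl_model: %d terms, sigma2 = %.4g>\n", x$n_terms, x$sigma2))
  if (x$n_terms > 0) cat("  terms:", paste(head(x$terms, 8), collapse = ", "),
                         if (x$n_terms > 8) "..." else "", "\n")
  invisible(x)
}
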