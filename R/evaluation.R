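# Experimental designs: parent-split cross-validation, close/distant training
# scenarios, learning curves, training-set replacement, QTL/weight
# cross-fitting and calibration summaries.

#' Build parent-split cross-validation folds for a diallel
#'
#' Splits each parental panel into two near-equal groups (odd sizes split
#' ceiling/floor, seeded random assignment); the four (row-group x
#' column-group) blocks of the diallel are the folds. Every hybrid in a block
#' shares no parent with the diagonally opposite block, which is what makes
#' the close/distant training scenarios possible.
#'
#' @param ped Pedigree tibble (`hybrid_id`, `parent_a`, `parent_alpha`).
#' @param seed Integer seed for the group assignment.
#' @return An object of class `cv_plan`: tibble `(hybrid_id, fold)` plus
#'   attributes `group_a` and `group_alpha` (named group vectors).
#' @export
build_cv_folds <- function(ped, seed = 1) {
  pa <- unique(ped$parent_a); pl <- unique(ped$parent_alpha)
  if (length(pa) < 2 || length(pl) < 2) {
    abort_arg("each parental panel needs >= 2 parents to split")
  }
  split_panel <- function(parents, tag) {
    with_seed(derive_seed(seed, "cv-split", tag), {
      shuffled <- sample(parents)
      g <- rep(1:2, c(ceiling(length(parents) / 2),
                      floor(length(parents) / 2)))
      setNames(g, shuffled)
    })
  }
  ga <- split_panel(pa, "a"); gl <- split_panel(pl, "alpha")
  # fold = 2 * (row group - 1) + column group
  plan <- ped |>
    mutate(fold = 2L * (ga[.data$parent_a] - 1L) + gl[.data$parent_alpha]) |>
    select("hybrid_id", "fold")
  structure(plan, class = c("cv_plan", class(plan)),
            group_a = ga, group_alpha = gl, seed = seed)
}

#' Assemble the training set for a fold under a training scenario
#'
#' For a fixed test fold (one block of the parent-split plan):
#' `"random"` trains on all non-test hybrids; `"distant"` trains on the
#' diagonally opposite block (no parent shared with any test individual);
#' `"close"` trains on a uniform sample, without replacement and of the same
#' size as the distant set, from the hybrids that share exactly one parent
#' with at least one test individual (the close pool is twice the distant
#' block, hence the downsampling).
#'
#' @param plan A `cv_plan`.
#' @param ped Pedigree tibble the plan was built from.
#' @param test_fold Fold number (1-4) used as test set.
#' @param scenario One of `"random"`, `"close"`, `"distant"`.
#' @param seed Integer seed for the close-pool downsample (redrawn per fold
#'   via a fold-indexed derived seed).
#' @return Character vector of training hybrid ids.
#' @export
build_training_scenario <- function(plan, ped, test_fold,
                                    scenario = c("random", "close", "distant"),
                                    seed = 1) {
  scenario <- match.arg(scenario)
  test_ids <- plan$hybrid_id[plan$fold == test_fold]
  if (length(test_ids) == 0) abort_arg(sprintf("empty test fold %s", test_fold))
  rest <- plan[plan$fold != test_fold, ]
  if (scenario == "random") return(rest$hybrid_id)
  shares <- shares_parent_with(ped, test_ids)
  names(shares) <- ped$hybrid_id
  distant_ids <- rest$hybrid_id[!shares[rest$hybrid_id]]
  if (scenario == "distant") return(distant_ids)
  close_pool <- rest$hybrid_id[shares[rest$hybrid_id]]
  n_want <- length(distant_ids)
  if (n_want > length(close_pool)) {
    abort_arg(sprintf("requested close sample (%d) exceeds available pool (%d)",
                      n_want, length(close_pool)))
  }
  with_seed(derive_seed(seed, "close-sample", test_fold),
            sample(close_pool, n_want))
}

# default fitting controls for the model zoo
dgp_control <- function(control = list()) {
  modifyList(list(max_terms = 50, max_int_terms = 20, inner_folds = 4,
                  mt_maxit = 200), control)
}

# fit one model on the training ids and predict the test ids for one trait;
# Y is the wide replicate-mean matrix, K the full grm
dgp_predict <- function(model, G, K, Y, ped, trait, train_ids, test_ids,
                        seed = 1, control = list()) {
  ctl <- dgp_control(control)
  y_tr <- Y[train_ids, trait]
  others <- setdiff(colnames(Y), trait)
  out <- switch(
    model,
    "P" = {
      fit <- fit_phenotype_regression(Y[train_ids, others, drop = FALSE], y_tr)
      tibble(hybrid_id = test_ids,
             pred_mean = predict(fit, Y[test_ids, others, drop = FALSE]),
             pred_sd = sqrt(fit$sigma2))
    },
    "BLUP" = blup_predict(K, y_tr, train_ids, test_ids),
    "QTL" = {
      fit <- fit_qtl_model(G[train_ids, , drop = FALSE], y_tr,
                           max_terms = ctl$max_terms, interactions = FALSE,
                           n_folds = ctl$inner_folds, seed = seed)
      pr <- predict(fit, G[test_ids, , drop = FALSE], se = TRUE)
      tibble(hybrid_id = test_ids, pred_mean = pr$pred_mean, pred_sd = pr$pred_sd)
    },
    "LMM" = {
      fit <- fit_lmm(G, K, y_tr, train_ids, interactions = TRUE,
                     max_terms = ctl$max_terms,
                     max_int_terms = ctl$max_int_terms,
                     n_folds = ctl$inner_folds, seed = seed)
      predict(fit, G, test_ids)
    },
    "LMM+P" = {
      fit <- fit_lmm_plus_p(Y[train_ids, others, drop = FALSE], y_tr, G, K,
                            train_ids, interactions = TRUE,
                            max_terms = ctl$max_terms,
                            max_int_terms = ctl$max_int_terms,
                            n_folds = ctl$inner_folds, seed = seed)
      predict(fit, G, Y[test_ids, others, drop = FALSE], test_ids)
    },
    "midparent" = {
      fit <- fit_midparent(ped, y_tr, train_ids)
      predict_midparent(fit, ped, test_ids) |> mutate(pred_sd = NA_real_)
    },
    "MT-LMM" = {
      all_ids <- c(train_ids, test_ids)
      F_all <- matrix(0, length(all_ids), ncol(Y),
                      dimnames = list(all_ids, colnames(Y)))
      for (tr_name in colnames(Y)) {
        qfit <- fit_qtl_model(G[train_ids, , drop = FALSE], Y[train_ids, tr_name],
                              max_terms = ctl$max_terms, interactions = TRUE,
                              max_int_terms = ctl$max_int_terms,
                              n_folds = ctl$inner_folds,
                              seed = derive_seed(seed, "mt-fx", tr_name))
        F_all[, tr_name] <- predict(qfit, G[all_ids, , drop = FALSE])
      }
      fit <- fit_mtlmm(Y[train_ids, , drop = FALSE],
                       F_all[train_ids, , drop = FALSE],
                       (if (inherits(K, "grm")) K$K else K)[train_ids, train_ids],
                       maxit = ctl$mt_maxit)
      predict_mtlmm(fit, K, F_all, Y[all_ids, , drop = FALSE],
                    train_ids, test_ids, trait)
    },
    abort_arg(sprintf("unknown model: %s", model))
  )
  out
}

#' Run a cross-validated prediction experiment
#'
#' Fits the chosen model on each fold's scenario training set, predicts the
#' held-out fold, and aggregates the coefficient of determination per trait,
#' both per fold and pooled over the four folds' test predictions.
#'
#' @param data A `diallel_data` (or a list with `G`, `pedigree`,
#'   `phenotypes`).
#' @param model One of `"P"`, `"BLUP"`, `"QTL"`, `"LMM"`, `"LMM+P"`,
#'   `"MT-LMM"`, `"midparent"`.
#' @param plan A `cv_plan`; built from the pedigree with `seed` when `NULL`.
#' @param scenario Training scenario, see [build_training_scenario()].
#' @param traits Traits to evaluate (default: all).
#' @param seed Integer seed (plan construction, inner CV, close downsampling).
#' @param control Fitting controls: `max_terms`, `max_int_terms`,
#'   `inner_folds`, `mt_maxit`.
#' @return An object of class `scenario_result`: list with `predictions`
#'   (per-individual), `by_fold` (trait x fold `r2`, `n_train`,
#'   `mean_pred_sd`, `resid_sd`) and `pooled` (per-trait pooled `r2`).
#' @export
run_crossval <- function(data, model = "BLUP", plan = NULL,
                         scenario = "random", traits = NULL, seed = 1,
                         control = list()) {
  ped <- data$pedigree
  Y <- phenotype_matrix(data$phenotypes, ped$hybrid_id)
  K <- compute_grm(data$G)
  if (is.null(plan)) plan <- build_cv_folds(ped, seed = seed)
  traits <- traits %||% colnames(Y)
  preds <- list()
  for (f in sort(unique(plan$fold))) {
    test_ids <- plan$hybrid_id[plan$fold == f]
    train_ids <- build_training_scenario(plan, ped, f, scenario, seed = seed)
    for (tr in traits) {
      p <- tryCatch(
        dgp_predict(model, data$G, K, Y, ped, tr, train_ids, test_ids,
                    seed = derive_seed(seed, "fold", f, tr),
                    control = control),
        error = function(e) {
          warn(sprintf("model %s failed on fold %d trait %s: %s",
                       model, f, tr, conditionMessage(e)))
          NULL
        })
      if (is.null(p)) next
      preds[[paste(f, tr)]] <- tibble(
        trait = tr, fold = f, hybrid_id = p$hybrid_id,
        obs = Y[p$hybrid_id, tr], pred_mean = p$pred_mean,
        pred_sd = p$pred_sd, n_train = length(train_ids))
    }
  }
  predictions <- bind_rows(preds)
  by_fold <- predictions |>
    group_by(.data$trait, .data$fold) |>
    summarise(r2 = r2_score(.data$obs, .data$pred_mean),
              n_train = .data$n_train[1],
              mean_pred_sd = sqrt(mean(.data$pred_sd^2)),
              resid_sd = sd(.data$obs - .data$pred_mean),
              .groups = "drop")
  pooled <- predictions |>
    group_by(.data$trait) |>
    summarise(r2 = r2_score(.data$obs, .data$pred_mean), .groups = "drop")
  structure(list(predictions = predictions, by_fold = by_fold,
                 pooled = pooled, model = model, scenario = scenario),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: model %s, scenario %s>\n", x$model, x$scenario))
  print(x$pooled)
  invisible(x)
}

#' @export
tidy.scenario_result <- function(x, ...) {
  x$by_fold |> mutate(model = x$model, scenario = x$scenario)
}

#' @export
glance.scenario_result <- function(x, ...) {
  tibble(model = x$model, scenario = x$scenario,
         median_r2 = median(x$pooled$r2), n_traits = nrow(x$pooled))
}

#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$r2, y = .data$trait)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = median, geom = "point", colour = "red",
                          shape = 124, size = 6) +
    ggplot2::labs(x = expression(R^2), y = NULL,
                  title = sprintf("%s (%s relatives)", object$model,
                                  object$scenario))
}

#' Learning curve over ordered training-set growth
#'
#' For each fold, orders the available training individuals by relatedness
#' class — close relatives first then distant (`"close_first"`), or the
#' reverse — and evaluates prediction accuracy at a grid of training sizes.
#' The crossover where the second class starts being added shows whether
#' distant relatives add information once close ones are present.
#'
#' @param data A `diallel_data`.
#' @param model Model name (default `"BLUP"`).
#' @param plan A `cv_plan` (built if `NULL`).
#' @param order `"close_first"` or `"distant_first"`.
#' @param sizes Integer vector of training sizes (0 allowed: the prediction is
#'   the mean phenotype of the available pool).
#' @param trait Trait to evaluate (default: first).
#' @param seed,control As in [run_crossval()].
#' @return A tibble of class `learning_curve` `(fold, size, n_close,
#'   n_distant, r2)`.
#' @export
learning_curve <- function(data, model = "BLUP", plan = NULL,
                           order = c("close_first", "distant_first"),
                           sizes = NULL, trait = NULL, seed = 1,
                           control = list()) {
  order <- match.arg(order)
  ped <- data$pedigree
  Y <- phenotype_matrix(data$phenotypes, ped$hybrid_id)
  K <- compute_grm(data$G)
  if (is.null(plan)) plan <- build_cv_folds(ped, seed = seed)
  trait <- trait %||% colnames(Y)[1]
  out <- list()
  for (f in sort(unique(plan$fold))) {
    test_ids <- plan$hybrid_id[plan$fold == f]
    rest <- plan$hybrid_id[plan$fold != f]
    shares <- shares_parent_with(ped, test_ids)
    names(shares) <- ped$hybrid_id
    close_pool <- with_seed(derive_seed(seed, "lc-close", f),
                            sample(rest[shares[rest]]))
    distant_pool <- with_seed(derive_seed(seed, "lc-distant", f),
                              sample(rest[!shares[rest]]))
    ordered_ids <- if (order == "close_first") c(close_pool, distant_pool)
                   else c(distant_pool, close_pool)
    sz <- sizes %||% unique(round(seq(0, length(ordered_ids), length.out = 9)))
    if (any(sz > length(ordered_ids))) {
      abort_arg("requested training size exceeds available individuals")
    }
    for (s in sz) {
      if (s == 0) {
        pred <- rep(mean(Y[ordered_ids, trait]), length(test_ids))
      } else {
        train_ids <- ordered_ids[seq_len(s)]
        pred <- dgp_predict(model, data$G, K, Y, ped, trait, train_ids,
                            test_ids, seed = derive_seed(seed, "lc", f, s),
                            control = control)$pred_mean
      }
      train_ids <- if (s == 0) character() else ordered_ids[seq_len(s)]
      out[[paste(f, s)]] <- tibble(
        fold = f, size = s,
        n_close = sum(train_ids %in% close_pool),
        n_distant = sum(train_ids %in% distant_pool),
        r2 = r2_score(Y[test_ids, trait], pred))
    }
  }
  structure(bind_rows(out), class = c("learning_curve", "tbl_df", "tbl",
                                      "data.frame"),
            model = model, order = order, trait = trait)
}

#' @export
autoplot.learning_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$r2,
                                       group = .data$fold)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$n_close > 0)) +
    ggplot2::labs(x = "training set size", y = expression(R^2),
                  colour = "close included",
                  title = sprintf("%s learning curve (%s)",
                                  attr(object, "model"), attr(object, "order")))
}

#' Replacement experiment: swap a fraction of distant training individuals
#'
#' Trains on the distant block, then swaps `ceiling(fraction * n_train)`
#' uniformly chosen training individuals for close relatives of the test set
#' (without replacement; the displaced individuals are removed, so the
#' training size is constant), and reports out-of-sample and in-sample
#' accuracy for both training sets.
#'
#' @param data A `diallel_data`.
#' @param model Model name (default `"QTL"`, the model the experiment is
#'   about).
#' @param plan A `cv_plan` (built if `NULL`).
#' @param fraction Fraction of the training set to replace (default 0.01).
#' @param trait Trait to evaluate (default: first).
#' @param seed,control As in [run_crossval()].
#' @return A tibble `(fold, regime, r2_out, r2_in, n_swapped)` with regimes
#'   `"distant"` and `"replaced"`.
#' @export
replacement_experiment <- function(data, model = "QTL", plan = NULL,
                                   fraction = 0.01, trait = NULL, seed = 1,
                                   control = list()) {
  if (!(fraction > 0 && fraction < 1)) abort_arg("`fraction` must be in (0, 1)")
  ped <- data$pedigree
  Y <- phenotype_matrix(data$phenotypes, ped$hybrid_id)
  K <- compute_grm(data$G)
  if (is.null(plan)) plan <- build_cv_folds(ped, seed = seed)
  trait <- trait %||% colnames(Y)[1]
  out <- list()
  for (f in sort(unique(plan$fold))) {
    test_ids <- plan$hybrid_id[plan$fold == f]
    distant_ids <- build_training_scenario(plan, ped, f, "distant", seed = seed)
    rest <- plan$hybrid_id[plan$fold != f]
    shares <- shares_parent_with(ped, test_ids)
    names(shares) <- ped$hybrid_id
    close_pool <- rest[shares[rest]]
    k <- ceiling(fraction * length(distant_ids))
    if (k > length(close_pool)) {
      abort_arg("not enough close relatives available for the swap")
    }
    swapped <- with_seed(derive_seed(seed, "swap", f), {
      drop_ids <- sample(distant_ids, k)
      add_ids <- sample(close_pool, k)
      c(setdiff(distant_ids, drop_ids), add_ids)
    })
    eval_set <- function(train_ids, regime) {
      pr_out <- dgp_predict(model, data$G, K, Y, ped, trait, train_ids,
                            test_ids, seed = derive_seed(seed, "rep", f, regime),
                            control = control)
      # in-sample: refit-free evaluation on the training individuals requires
      # predictions for them; fit once more with itself as "test" via OLS
      # reuse: the QTL model's in-sample predictions come from the same fit
      fit_in <- fit_qtl_model(data$G[train_ids, , drop = FALSE],
                              Y[train_ids, trait],
                              max_terms = dgp_control(control)$max_terms,
                              interactions = FALSE,
                              n_folds = dgp_control(control)$inner_folds,
                              seed = derive_seed(seed, "rep-in", f, regime))
      tibble(fold = f, regime = regime,
             r2_out = r2_score(Y[test_ids, trait], pr_out$pred_mean),
             r2_in = r2_score(Y[train_ids, trait],
                              predict(fit_in, data$G[train_ids, , drop = FALSE])),
             n_swapped = if (regime == "replaced") k else 0L)
    }
    out[[paste(f, 1)]] <- eval_set(distant_ids, "distant")
    out[[paste(f, 2)]] <- eval_set(swapped, "replaced")
  }
  bind_rows(out)
}

#' QTL mapping / weight estimation cross-fitting experiment
#'
#' Separates the two stages of the QTL model: terms are selected (mapping, by
#' double cross-validation) on training set A, then their weights are refit by
#' OLS, term set fixed, on training set B, and the model is evaluated on the
#' test fold. All four combinations of A, B in close/distant are reported,
#' isolating whether low distant-relative accuracy comes from the mapped loci
#' or from their estimated effects.
#'
#' @param data A `diallel_data`.
#' @param plan A `cv_plan` (built if `NULL`).
#' @param trait Trait to evaluate (default: first).
#' @param seed,control As in [run_crossval()].
#' @return A tibble `(fold, map, weights, r2)`.
#' @export
cross_fit_experiment <- function(data, plan = NULL, trait = NULL, seed = 1,
                                 control = list()) {
  ped <- data$pedigree
  Y <- phenotype_matrix(data$phenotypes, ped$hybrid_id)
  if (is.null(plan)) plan <- build_cv_folds(ped, seed = seed)
  trait <- trait %||% colnames(Y)[1]
  ctl <- dgp_control(control)
  out <- list()
  for (f in sort(unique(plan$fold))) {
    test_ids <- plan$hybrid_id[plan$fold == f]
    sets <- list(
      close = build_training_scenario(plan, ped, f, "close", seed = seed),
      distant = build_training_scenario(plan, ped, f, "distant", seed = seed))
    maps <- lapply(sets, function(ids) {
      fit_qtl_model(data$G[ids, , drop = FALSE], Y[ids, trait],
                    max_terms = ctl$max_terms, interactions = FALSE,
                    n_folds = ctl$inner_folds,
                    seed = derive_seed(seed, "xfit", f))
    })
    for (map_in in names(sets)) for (w_in in names(sets)) {
      terms <- maps[[map_in]]$terms
      ids_b <- sets[[w_in]]
      refit <- fit_qtl_weights(term_columns(data$G[ids_b, , drop = FALSE], terms),
                               Y[ids_b, trait])
      pred <- predict(refit, data$G[test_ids, , drop = FALSE])
      out[[paste(f, map_in, w_in)]] <- tibble(
        fold = f, map = map_in, weights = w_in,
        r2 = r2_score(Y[test_ids, trait], pred))
    }
  }
  bind_rows(out)
}

#' Calibration summary of predictive uncertainty
#'
#' For each trait x scenario cell, pairs the model-derived predictive standard
#' deviation (square root of the mean predictive variance over test
#' individuals) with the realized residual standard deviation of the test
#' predictions, and summarises agreement across cells: the squared Pearson
#' correlation and the through-origin slope of squared residual SD on mean
#' predictive variance. A slope near 1 means the model-derived uncertainties
#' match the realized errors.
#'
#' @param results A `scenario_result` or a list of them.
#' @return A tibble `(trait, scenario, model, pred_sd, resid_sd)` with
#'   attributes `r2` and `slope`.
#' @export
calibration_summary <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  cells <- purrr::map(results, function(res) {
    res$predictions |>
      group_by(.data$trait) |>
      summarise(pred_sd = sqrt(mean(.data$pred_sd^2)),
                resid_sd = sd(.data$obs - .data$pred_mean),
                .groups = "drop") |>
      mutate(scenario = res$scenario, model = res$model)
  }) |> bind_rows()
  if (nrow(cells) < 3) abort_arg("calibration needs >= 3 (trait, scenario) points")
  if (sd(cells$pred_sd) < 1e-12) {
    abort_arg("predictive SDs are all equal; calibration correlation undefined")
  }
  fit <- lm(I(resid_sd^2) ~ 0 + I(pred_sd^2), data = cells)
  structure(cells,
            r2 = cor(cells$pred_sd, cells$resid_sd)^2,
            slope = unname(coef(fit)[1]),
            class = c("calibration_summary", class(cells)))
}

#' @export
autoplot.calibration_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pred_sd, y = .data$resid_sd,
                                       colour = .data$scenario)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = "predictive SD (model-derived)",
                  y = "residual SD (observed)",
                  subtitle = sprintf("r² = %.2f, slope = %.2f",
                                     attr(object, "r2"), attr(object, "slope")))
}
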