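# Stacked cross-prediction age estimation and BAG computation.
#
# The estimation design: the cohort is split into k folds; in each repeat
# every individual is predicted exactly once by models trained without them
# (PCA fitted on the training folds only). Learner predictions are stacked
# within tissue by an OLS meta-model fitted on nested out-of-fold
# predictions; the combined estimate stacks the tissue-level predictions;
# repeat-level estimates are averaged at the end.

#' Cross-prediction plan
#'
#' @param n_folds Outer cross-prediction folds (default 10).
#' @param n_repeats Number of repeats of the full fold cycle. The study-scale
#'   value is 100; the package default is desk-scale.
#' @param n_components PCA components retained per tissue (0 = no PCA). The
#'   study-scale value is 500.
#' @param learners Named list of learner specs (see [learner_ridge()]).
#' @param stacking_folds Nested folds for the stacking meta-model.
#' @param seed Integer seed controlling all fold assignments.
#' @return List of class `"crossprediction_plan"`.
#' @export
crossprediction_plan <- function(n_folds = 10, n_repeats = 5,
                                 n_components = 50,
                                 learners = default_learners(),
                                 stacking_folds = 10, seed = 1L) {
  if (n_folds < 2) stop("`n_folds` must be >= 2", call. = FALSE)
  if (is.null(names(learners)) || any(names(learners) == ""))
    names(learners) <- paste0("learner", seq_along(learners))
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 n_components = as.integer(n_components),
                 learners = learners,
                 stacking_folds = as.integer(stacking_folds),
                 seed = as.integer(seed)),
            class = "crossprediction_plan")
}

#' Built-in learners
#'
#' A learner spec is a list with a `fit(X, y)` function returning a model
#' and a `predict(model, X)` function returning numeric predictions.
#' `learner_ridge()` is an L2-penalized linear model (glmnet, alpha = 0);
#' `learner_xgboost()` is gradient boosting (tree or linear booster);
#' `learner_lm()` is plain OLS; `learner_column(j)` predicts feature column
#' `j` verbatim (an oracle for leakage tests, used with `n_components = 0`).
#'
#' @param lambda Ridge penalty.
#' @param nrounds,eta,max_depth,booster xgboost parameters.
#' @param j Feature column index.
#' @return A learner spec.
#' @export
learner_ridge <- function(lambda = 0.01) {
  list(fit = function(X, y)
         glmnet::glmnet(X, y, alpha = 0, lambda = lambda),
       predict = function(m, X)
         as.vector(stats::predict(m, newx = X, s = lambda)))
}

#' @rdname learner_ridge
#' @export
learner_xgboost <- function(nrounds = 60, eta = 0.1, max_depth = 3,
                            booster = c("gbtree", "gblinear")) {
  booster <- match.arg(booster)
  list(fit = function(X, y)
         xgboost::xgboost(data = X, label = y, nrounds = nrounds,
                          params = list(booster = booster, eta = eta,
                                        max_depth = max_depth,
                                        nthread = 1),
                          verbose = 0),
       predict = function(m, X) as.vector(stats::predict(m, X)))
}

#' @rdname learner_ridge
#' @export
learner_lm <- function() {
  list(fit = function(X, y) stats::lm.fit(cbind(1, X), y)$coefficients,
       predict = function(m, X) as.vector(cbind(1, X) %*% m))
}

#' @rdname learner_ridge
#' @export
learner_column <- function(j = 1) {
  list(fit = function(X, y) j,
       predict = function(m, X) X[, m])
}

#' @rdname learner_ridge
#' @export
default_learners <- function() {
  list(ridge = learner_ridge(), gbt = learner_xgboost())
}

# Seeded fold assignment: permute individuals, folds as equal as possible,
# remainder distributed to the first folds.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  unname(rep(seq_len(k), times = sizes))[order(sample.int(n))]
}

#' Out-of-fold cross-prediction of age from imaging features
#'
#' For every repeat, every individual is predicted exactly once by models
#' trained without them. PCA (when `n_components > 0`) is fitted on the
#' training folds only and its rotation applied to the held-out fold.
#'
#' @param features_by_tissue Named list of numeric feature matrices, rows
#'   aligned with `age`.
#' @param age Chronological age vector.
#' @param plan A [crossprediction_plan()].
#' @return Array `[individual, learner, tissue, repeat]` of out-of-fold
#'   predictions, with dimnames.
#' @export
crosspredict_ensemble <- function(features_by_tissue, age, plan) {
  stopifnot(inherits(plan, "crossprediction_plan"))
  n <- length(age)
  if (any(vapply(features_by_tissue, nrow, 1L) != n))
    stop("features must be row-aligned with `age`", call. = FALSE)
  if (any(vapply(features_by_tissue, anyNA, TRUE)) || anyNA(age))
    stop("missing values are not supported", call. = FALSE)
  if (n < plan$n_folds)
    stop("fewer individuals than folds", call. = FALSE)
  tissues <- names(features_by_tissue)
  L <- length(plan$learners)
  oof <- array(NA_real_, c(n, L, length(tissues), plan$n_repeats),
               dimnames = list(NULL, names(plan$learners), tissues, NULL))
  for (r in seq_len(plan$n_repeats)) {
    fold <- make_folds(n, plan$n_folds, plan$seed + 1000L * r)
    for (f in seq_len(plan$n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      for (t in seq_along(tissues)) {
        X <- features_by_tissue[[t]]
        if (plan$n_components > 0) {
          pc <- stats::prcomp(X[tr, , drop = FALSE], center = TRUE,
                              scale. = FALSE)
          k <- min(plan$n_components, ncol(pc$rotation))
          Xtr <- pc$x[, seq_len(k), drop = FALSE]
          Xte <- scale(X[te, , drop = FALSE], center = pc$center,
                       scale = FALSE) %*% pc$rotation[, seq_len(k),
                                                      drop = FALSE]
        } else {
          Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        }
        for (l in seq_len(L)) {
          lr <- plan$learners[[l]]
          set.seed(plan$seed + 7L * r + 13L * f + 29L * l)
          mdl <- lr$fit(Xtr, age[tr])
          oof[te, l, t, r] <- lr$predict(mdl, Xte)
        }
      }
    }
  }
  oof
}

# Nested out-of-fold OLS stacking of the columns of P against y.
# With a single column the input passes through unchanged (meta-weight 1).
stack_ols <- function(P, y, k, seed) {
  P <- as.matrix(P)
  if (ncol(P) == 1) return(as.vector(P))
  n <- length(y)
  fold <- make_folds(n, k, seed)
  out <- numeric(n)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    cf <- stats::lm.fit(cbind(1, P[tr, , drop = FALSE]), y[tr])$coefficients
    cf[is.na(cf)] <- 0
    out[te] <- cbind(1, P[te, , drop = FALSE]) %*% cf
  }
  out
}

#' Stack out-of-fold predictions into tissue-level and combined estimates
#'
#' Within each tissue and repeat, learner predictions are combined by an OLS
#' meta-model fitted on nested out-of-fold predictions; the combined estimate
#' stacks the tissue-level predictions the same way. Repeat-level estimates
#' are then averaged to one value per tissue-trait per individual.
#'
#' @param oof Prediction array from [crosspredict_ensemble()].
#' @param age Chronological age.
#' @param plan The [crossprediction_plan()].
#' @return List of class `"stacked_age_estimate"`: `pred` (data.frame with
#'   one column per tissue plus `combined`), `per_repeat` (array
#'   `[individual, tissue + combined, repeat]`), `tensor` (the input array).
#' @export
stack_predictions <- function(oof, age, plan) {
  n <- dim(oof)[1]; tissues <- dimnames(oof)[[3]]; R <- dim(oof)[4]
  if (length(tissues) < 2)
    stop("combined estimate requires at least two tissues", call. = FALSE)
  if (anyNA(oof)) stop("prediction tensor is incomplete", call. = FALSE)
  per_rep <- array(NA_real_, c(n, length(tissues) + 1, R),
                   dimnames = list(NULL, c(tissues, "combined"), NULL))
  for (r in seq_len(R)) {
    tp <- sapply(seq_along(tissues), function(t)
      stack_ols(oof[, , t, r], age, plan$stacking_folds,
                plan$seed + 501L * r + t))
    per_rep[, seq_along(tissues), r] <- tp
    per_rep[, length(tissues) + 1, r] <-
      stack_ols(tp, age, plan$stacking_folds, plan$seed + 501L * r + 99L)
  }
  pred <- as.data.frame(apply(per_rep, c(1, 2), mean))
  structure(list(pred = pred, per_repeat = per_rep, tensor = oof),
            class = "stacked_age_estimate")
}

#' Compute raw and covariate-adjusted brain age gap
#'
#' `bag_raw = predicted age - chronological age`. Because of regression
#' dilution, raw BAG is negatively correlated with age (younger individuals
#' get higher, older lower values); `bag_adj` is the OLS residual of
#' `bag_raw` on the covariates (which should include age and age squared),
#' removing that bias.
#'
#' @param estimate A `"stacked_age_estimate"` or a data.frame of predicted
#'   ages (one column per tissue-trait).
#' @param age Chronological age.
#' @param covariates Data frame of covariates (sex, age, age^2, site, TIV,
#'   ... ); factors are dummy-coded. Individuals with missing covariate
#'   values are dropped with a message.
#' @return Data frame of class `"bag_table"`: id row index, per trait
#'   `bag_raw_<trait>` and `bag_adj_<trait>`, plus attribute `"covariates"`.
#' @export
compute_bag <- function(estimate, age, covariates) {
  pred <- if (inherits(estimate, "stacked_age_estimate"))
    estimate$pred else as.data.frame(estimate)
  covariates <- as.data.frame(covariates)
  keep <- stats::complete.cases(covariates)
  if (!all(keep))
    message(sum(!keep), " individual(s) dropped for missing covariates")
  C <- covariate_matrix(covariates[keep, , drop = FALSE])
  out <- data.frame(row = which(keep))
  for (tr in colnames(pred)) {
    raw <- pred[keep, tr] - age[keep]
    out[[paste0("bag_raw_", tr)]] <- raw
    out[[paste0("bag_adj_", tr)]] <- as.vector(residualize(raw, C))
  }
  structure(out, covariates = colnames(covariates), class = c("bag_table",
            "data.frame"))
}

#' Default BAG covariate set from a cohort table
#'
#' sex, age, age^2, scanner site (factor), TIV, genotyping array (factor)
#' and the genetic principal components present in the table.
#'
#' @param cohort Cohort data frame from [simulate_cohort()].
#' @return Covariate data frame.
#' @export
default_covariates <- function(cohort) {
  pcs <- grep("^pc", names(cohort), value = TRUE)
  out <- data.frame(sex = cohort$sex, age = cohort$age,
                    age2 = cohort$age^2, site = factor(cohort$site),
                    tiv = cohort$tiv, array = factor(cohort$array))
  cbind(out, cohort[, pcs, drop = FALSE])
}

#' Age-prediction performance metrics
#'
#' Product-moment correlation `r`, coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot` (no refit; can be negative and is not the
#' square of `r`), mean absolute error in years, and, when a retest is
#' supplied, the two-way mixed-effects consistency single-measurement
#' intraclass correlation ICC(C,1).
#'
#' @param pred Predicted age.
#' @param age Chronological age.
#' @param retest_pred Optional retest predictions; `pred`/`retest_pred` are
#'   then the two sessions of the same individuals.
#' @return List: `r`, `r2`, `mae`, `icc` (NA without retest).
#' @export
model_metrics <- function(pred, age, retest_pred = NULL) {
  if (length(pred) != length(age))
    stop("`pred` and `age` lengths differ", call. = FALSE)
  r <- stats::cor(pred, age)
  r2 <- 1 - sum((age - pred)^2) / sum((age - mean(age))^2)
  mae <- mean(abs(pred - age))
  icc <- NA_real_
  if (!is.null(retest_pred)) icc <- icc_c1(cbind(pred, retest_pred))
  list(r = r, r2 = r2, mae = mae, icc = icc)
}

#' ICC(C,1): two-way mixed-effects, consistency, single measurement
#'
#' `(MS_rows - MS_err) / (MS_rows + (k - 1) MS_err)` from the two-way ANOVA
#' decomposition of an n-subjects-by-k-sessions matrix.
#'
#' @param m Numeric matrix, rows = subjects, columns = sessions.
#' @return ICC(C,1) value.
#' @export
icc_c1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}
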