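#' Boosting hyperparameters
#'
#' The tunable knobs of the stochastic gradient-boosted classifier. The
#' customary search ranges are 1000-2000 trees, 6-20 nodes per tree and 2-50
#' minimum cases per terminal node; values outside those ranges are allowed
#' but flagged with a warning. The learning rate defaults to 0.01, paired
#' with 1000 trees.
#'
#' @param n_trees number of boosting iterations.
#' @param max_nodes maximum terminal nodes (leaves) per tree.
#' @param min_cases minimum cases per terminal node.
#' @param learning_rate shrinkage per tree.
#' @param class_balance if TRUE, class weights are inversely proportional to
#'   class frequencies so unequal presence/pseudo-absence counts contribute
#'   equally to the loss.
#' @param subsample fraction of rows drawn (without replacement) per tree;
#'   the stochastic element of the boosting.
#' @return a `hyperparameters` list.
#' @export
hyperparameters <- function(n_trees = 1000, max_nodes = 6, min_cases = 10,
                            learning_rate = 0.01, class_balance = TRUE,
                            subsample = 0.5) {
  if (n_trees < 1000 || n_trees > 2000)
    warning("n_trees = ", n_trees, " is outside the usual 1000-2000 range")
  if (max_nodes < 6 || max_nodes > 20)
    warning("max_nodes = ", max_nodes, " is outside the usual 6-20 range")
  if (min_cases < 2 || min_cases > 50)
    warning("min_cases = ", min_cases, " is outside the usual 2-50 range")
  structure(list(n_trees = as.integer(n_trees),
                 max_nodes = as.integer(max_nodes),
                 min_cases = as.integer(min_cases),
                 learning_rate = learning_rate,
                 class_balance = isTRUE(class_balance),
                 subsample = subsample),
            class = "hyperparameters")
}

.predictor_columns <- function(data, predictors = NULL) {
  if (!is.null(predictors)) return(predictors)
  drop <- c("label", "season", "season_year", "cell", "x", "y", "lon", "lat",
            "animal_id", "timestamp")
  setdiff(names(data), drop)
}

.model_matrix <- function(data, predictors) {
  m <- as.matrix(data[, predictors, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit a boosted-tree niche model
#'
#' Fits a stochastic gradient-boosted ensemble of small decision trees with
#' binomial (log-loss) deviance to a presence/pseudo-absence training table,
#' the engine behind every seasonal and annual distribution model in the
#' package. Trees are grown sequentially on the residual gradient with random
#' row subsampling; with `class_balance` on, the minority class is upweighted
#' so both classes contribute equally. Rows with missing predictor values are
#' excluded with a message.
#'
#' The returned object carries the fitted ensemble, relative variable
#' importances rescaled so the top predictor scores exactly 100, the balanced
#' presence/absence threshold computed on the full training table, and a
#' validation report (AUC, percent correct at the balanced threshold, and a
#' verbal accuracy grade) computed on the held-out `test` rows when supplied,
#' otherwise on the training rows.
#'
#' @param train training table with a `label` column (1/0) and predictor
#'   columns.
#' @param test optional held-out rows (same columns) used for the report.
#' @param hp a [hyperparameters] object.
#' @param predictors predictor column names; default: every column except
#'   the bookkeeping ones.
#' @param seed integer seed; fits are deterministic (single-threaded).
#' @return an object of class `niche_model`.
#' @seealso [predict.niche_model], [variable_importance],
#'   [partial_dependence], [balanced_threshold]
#' @export
fit_niche <- function(train, test = NULL, hp = hyperparameters(),
                      predictors = NULL, seed = 1) {
  if (!nrow(train)) stop("empty training table")
  if (length(unique(train$label)) < 2)
    stop("both classes must be present in the training data")
  predictors <- .predictor_columns(train, predictors)
  if (!length(predictors)) stop("no predictor columns")
  keep <- stats::complete.cases(train[, predictors, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " row(s) with missing predictor values excluded")
  train <- train[keep, , drop = FALSE]
  x <- .model_matrix(train, predictors)
  y <- as.numeric(train$label)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  params <- xgboost::xgb.params(
    objective = "binary:logistic",
    eta = hp$learning_rate,
    tree_method = "hist",
    grow_policy = "lossguide",
    max_depth = 0L,
    max_leaves = hp$max_nodes,
    min_child_weight = hp$min_cases,
    subsample = hp$subsample,
    scale_pos_weight = if (hp$class_balance) n0 / n1 else 1,
    nthread = 1L,
    seed = derive_seed(seed, "boost"))
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(params, dtrain, nrounds = hp$n_trees,
                                verbose = 0)
  model <- structure(
    list(booster = booster, predictors = predictors, hp = hp, seed = seed,
         train_x = x, train_y = y, n_train = nrow(train)),
    class = "niche_model")
  model$importance <- variable_importance(model)
  scores_train <- predict(model, train)
  model$balanced_threshold <- balanced_threshold(y, scores_train)
  eval_data <- if (!is.null(test) && nrow(test)) test else train
  eval_scores <- if (is.null(test) || !nrow(test)) scores_train
                 else predict(model, test)
  pc <- percent_correct(eval_data$label, eval_scores,
                        model$balanced_threshold)
  model$report <- list(
    auc = auc(eval_data$label, eval_scores),
    pct_correct = pc,
    grade = grade_model(pc),
    balanced_threshold = model$balanced_threshold,
    holdout = !is.null(test) && nrow(test) > 0,
    n_test = if (is.null(test)) 0L else nrow(test))
  model
}

#' Predict from a niche model
#'
#' @param object a `niche_model`.
#' @param newdata data.frame or matrix holding the model's predictor
#'   columns.
#' @param type `"response"` for scores in `[0, 1]` (the RIO scale) or
#'   `"link"` for the latent log-odds.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.niche_model <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss))
    stop("newdata is missing predictor column(s): ",
         paste(miss, collapse = ", "))
  x <- if (is.matrix(newdata)) newdata[, object$predictors, drop = FALSE]
       else .model_matrix(newdata, object$predictors)
  stats::predict(object$booster, xgboost::xgb.DMatrix(x),
                 outputmargin = (type == "link"))
}

#' @export
print.niche_model <- function(x, ...) {
  cat("Boosted-tree niche model\n")
  cat(sprintf("  %d trees, <=%d nodes/tree, min %d cases/node, eta %g%s\n",
              x$hp$n_trees, x$hp$max_nodes, x$hp$min_cases,
              x$hp$learning_rate,
              if (x$hp$class_balance) ", balanced classes" else ""))
  cat(sprintf("  trained on %d rows (%d presences), %d predictors\n",
              x$n_train, sum(x$train_y == 1), length(x$predictors)))
  r <- x$report
  cat(sprintf("  %s AUC = %.3f, %.2f%% correct ('%s') at threshold %.2f\n",
              if (r$holdout) "holdout" else "training",
              r$auc, 100 * r$pct_correct, r$grade, r$balanced_threshold))
  invisible(x)
}

#' @export
summary.niche_model <- function(object, n_top = 10, ...) {
  print(object)
  imp <- sort(object$importance, decreasing = TRUE)
  cat("\nTop predictors (relative importance, max = 100):\n")
  for (k in seq_len(min(n_top, length(imp))))
    cat(sprintf("  %2d. %-24s %6.1f\n", k, names(imp)[k], imp[k]))
  invisible(object)
}

#' @export
coef.niche_model <- function(object, ...) object$importance

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability a random presence scores
#' above a random absence, counting ties as half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Overall classification accuracy at a threshold
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold score cutoff in `[0, 1]`; prediction is
#'   `score >= threshold`.
#' @return fraction `(TP + TN) / n`.
#' @export
percent_correct <- function(labels, scores, threshold) {
  if (!length(labels)) stop("empty input")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  mean((scores >= threshold) == (as.numeric(labels) == 1))
}

#' Verbal accuracy grade
#'
#' Bins overall accuracy into the conventional model grades: at least 0.90
#' is "excellent", at least 0.80 "good", at least 0.70 "fair", below 0.70
#' "poor" (exact boundaries take the higher grade).
#'
#' @param pct_correct accuracy in `[0, 1]`.
#' @return one of `"excellent"`, `"good"`, `"fair"`, `"poor"`.
#' @export
grade_model <- function(pct_correct) {
  if (is.na(pct_correct) || pct_correct < 0 || pct_correct > 1)
    stop("pct_correct must be in [0, 1]")
  if (pct_correct >= 0.90) "excellent"
  else if (pct_correct >= 0.80) "good"
  else if (pct_correct >= 0.70) "fair"
  else "poor"
}

#' Relative variable importance
#'
#' Split-gain importance of every predictor, rescaled so the top predictor
#' scores exactly 100.0; predictors the ensemble never splits on score 0.
#' The rescaling is a monotone transform, so the ranking is that of the raw
#' gains.
#'
#' @param model a `niche_model`.
#' @return named numeric vector over all predictors, descending order not
#'   guaranteed (named by predictor).
#' @export
variable_importance <- function(model) {
  if (is.null(model$booster)) stop("unfitted model")
  # xgb.importance mis-parses single-feature boosters; total split gain from
  # the tree dump is the same statistic
  imp <- tryCatch(
    as.data.frame(xgboost::xgb.importance(model = model$booster)),
    error = function(e) {
      dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
      dt <- dt[dt$Feature != "Leaf", , drop = FALSE]
      if (!nrow(dt)) return(data.frame(Feature = character(0),
                                       Gain = numeric(0)))
      stats::aggregate(Gain ~ Feature, data = dt, FUN = sum)
    })
  out <- setNames(numeric(length(model$predictors)), model$predictors)
  if (nrow(imp)) out[imp$Feature] <- imp$Gain
  if (max(out) > 0) out <- out / max(out) * 100
  out
}

#' Partial dependence of the model on one predictor
#'
#' Friedman partial dependence on the latent (log-odds) scale: for each grid
#' value `v`, the predictor column is forced to `v` in every training row and
#' the model's latent predictions are averaged; the curve is centred to mean
#' zero over the evaluation grid so curves are comparable across predictors.
#' Positive stretches mark predictor ranges associated with predicted
#' occurrence.
#'
#' @param model a `niche_model`.
#' @param predictor predictor name.
#' @param eval_grid numeric grid of predictor values; default 50 equally
#'   spaced points over the observed range.
#' @param data rows to average over; default the training rows.
#' @return a `pd_curve` data.frame with columns `value` and `pd`, attribute
#'   `predictor`.
#' @export
partial_dependence <- function(model, predictor, eval_grid = NULL,
                               data = NULL) {
  if (!predictor %in% model$predictors)
    stop("predictor '", predictor, "' is not in the model")
  x <- if (is.null(data)) model$train_x
       else .model_matrix(data, model$predictors)
  if (is.null(eval_grid)) {
    rng <- range(x[, predictor])
    eval_grid <- seq(rng[1], rng[2], length.out = 50)
  }
  if (!length(eval_grid)) stop("empty eval_grid")
  if (is.unsorted(eval_grid, strictly = TRUE))
    eval_grid <- sort(unique(eval_grid))
  n <- nrow(x); m <- length(eval_grid)
  # one prediction call over the stacked forced copies
  big <- x[rep(seq_len(n), m), , drop = FALSE]
  big[, predictor] <- rep(eval_grid, each = n)
  lat <- stats::predict(model$booster, xgboost::xgb.DMatrix(big),
                        outputmargin = TRUE)
  pd <- colMeans(matrix(lat, nrow = n, ncol = m))
  pd <- pd - mean(pd)
  structure(data.frame(value = eval_grid, pd = pd),
            predictor = predictor, class = c("pd_curve", "data.frame"))
}

#' Positive association ranges of a partial-dependence curve
#'
#' Maximal contiguous runs of evaluation-grid points where the centred curve
#' is positive: the predictor ranges associated with predicted occurrence
#' (e.g. "presence above 70 mm of winter precipitation" reads off as a single
#' interval whose lower endpoint is the response threshold).
#'
#' @param curve a `pd_curve` from [partial_dependence].
#' @return data.frame with columns `lo` and `hi` (grid values); zero rows if
#'   the curve is nowhere positive.
#' @export
extract_association_ranges <- function(curve) {
  if (!nrow(curve)) stop("empty curve")
  pos <- curve$pd > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(lo = curve$value[starts[keep]], hi = curve$value[ends[keep]])
}

#' Plot a niche model's partial dependence
#'
#' @param x a `niche_model`.
#' @param predictor predictor to plot; default the most important one.
#' @param ... passed to [partial_dependence].
#' @export
plot.niche_model <- function(x, predictor = NULL, ...) {
  if (is.null(predictor))
    predictor <- names(which.max(x$importance))
  pd <- partial_dependence(x, predictor, ...)
  graphics::plot(pd$value, pd$pd, type = "l",
                 xlab = predictor, ylab = "partial dependence (log-odds)",
                 main = sprintf("Partial dependence: %s", predictor))
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(pd)
}

#' Tune hyperparameters on a holdout
#'
#' Fits one model per grid point and evaluates each on the held-out test
#' rows. The best model maximises holdout AUC; ties break to the lowest
#' misclassification rate at the balanced threshold, then to the smallest
#' ensemble.
#'
#' @param train,test training and held-out tables.
#' @param grid list of [hyperparameters] objects (at least one).
#' @param seed integer seed shared across fits.
#' @return list with `best` (a `niche_model`) and `tuning` (one row per grid
#'   point: hyperparameters, auc, pct_correct).
#' @export
tune_hyperparameters <- function(train, test, grid, seed = 1) {
  if (!length(grid)) stop("empty hyperparameter grid")
  rows <- vector("list", length(grid))
  models <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    hp <- grid[[k]]
    m <- fit_niche(train, test, hp = hp, seed = seed)
    models[[k]] <- m
    rows[[k]] <- data.frame(n_trees = hp$n_trees, max_nodes = hp$max_nodes,
                            min_cases = hp$min_cases,
                            learning_rate = hp$learning_rate,
                            auc = m$report$auc,
                            pct_correct = m$report$pct_correct)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$auc, 1 - tab$pct_correct, tab$n_trees)
  list(best = models[[ord[1]]], tuning = tab)
}

#' Default tuning grid
#'
#' The standard search lattice: trees in {1000, 1500, 2000}, nodes per tree
#' in {6, 12, 20}, minimum cases in {2, 10, 50}.
#'
#' @param learning_rate shared learning rate.
#' @return list of [hyperparameters].
#' @export
default_tuning_grid <- function(learning_rate = 0.01) {
  g <- expand.grid(n_trees = c(1000L, 1500L, 2000L),
                   max_nodes = c(6L, 12L, 20L),
                   min_cases = c(2L, 10L, 50L))
  lapply(seq_len(nrow(g)), function(k)
    hyperparameters(g$n_trees[k], g$max_nodes[k], g$min_cases[k],
                    learning_rate = learning_rate))
}
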