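test_that("AUC equals the Mann-Whitney pair statistic", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0.0)
  expect_equal(auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3)), 0.75)
  expect_error(auc(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("AUC matches exhaustive pair counting on all small inputs", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("percent correct counts the confusion matrix", {
  expect_equal(percent_correct(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2), 0.5), 1)
  expect_equal(percent_correct(c(1, 1, 1), c(0.1, 0.5, 0.9), 0), 1)
  # 6-row worked set: preds at 0.5 are 1,1,0 | 1,0,0 -> TP=2, TN=2
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.6, 0.2, 0.7, 0.3, 0.1)
  expect_equal(percent_correct(labels, scores, 0.5), 4 / 6)
  expect_error(percent_correct(numeric(0), numeric(0), 0.5), "empty")
  expect_error(percent_correct(1, 0.5, 2), "threshold")
})

test_that("accuracy grades bin with boundaries to the higher grade", {
  expect_identical(grade_model(0.9353), "excellent")
  expect_identical(grade_model(0.8845), "good")
  expect_identical(grade_model(0.75), "fair")
  expect_identical(grade_model(0.90), "excellent")
  expect_identical(grade_model(0.80), "good")
  expect_identical(grade_model(0.70), "fair")
  expect_identical(grade_model(0.5), "poor")
  expect_error(grade_model(1.2), "must be in")
})

test_that("the boosted fit separates a separable toy perfectly", {
  m <- toy_model()
  expect_equal(m$report$auc, 1.0)
  expect_true(all(predict(m, separable_toy()) >= 0 &
                    predict(m, separable_toy()) <= 1))
})

test_that("fits are deterministic per seed and reject degenerate input", {
  tab <- separable_toy(100)
  m1 <- toy_model(100, seed = 7)
  m2 <- toy_model(100, seed = 7)
  expect_identical(predict(m1, tab), predict(m2, tab))
  expect_error(suppressWarnings(
    fit_niche(data.frame(label = rep(1, 20), x = rnorm(20)))), "both classes")
  expect_error(fit_niche(data.frame(label = integer(0), x = numeric(0))),
               "empty")
})

test_that("shuffled labels yield chance-level holdout AUC", {
  set.seed(55)
  n <- 2000
  tab <- data.frame(label = sample(rep(0:1, n / 2)),
                    x1 = rnorm(n), x2 = rnorm(n))
  sp <- split_train_test(tab, 0.2, seed = 55)
  m <- suppressWarnings(fit_niche(
    sp$train, sp$test,
    hp = hyperparameters(n_trees = 150, max_nodes = 6, min_cases = 10,
                         learning_rate = 0.05), seed = 55))
  expect_gt(m$report$auc, 0.4)
  expect_lt(m$report$auc, 0.6)
})

test_that("importance rescales the top predictor to exactly 100", {
  m <- toy_model()
  imp <- variable_importance(m)
  expect_equal(max(imp), 100.0)
  expect_identical(names(which.max(imp)), "x1")
  expect_true(all(imp >= 0 & imp <= 100))
  # single-predictor model: that predictor scores 100
  tab <- separable_toy(100)[, c("label", "x1")]
  m1 <- suppressWarnings(fit_niche(tab, hp = hyperparameters(
    n_trees = 30, max_nodes = 4, min_cases = 5, learning_rate = 0.3),
    seed = 1))
  expect_equal(unname(variable_importance(m1)), 100.0)
})

test_that("importance ordering is the raw gain ordering", {
  m <- toy_model()
  raw <- xgboost::xgb.importance(model = m$booster)
  resc <- sort(variable_importance(m), decreasing = TRUE)
  expect_identical(names(resc)[seq_len(nrow(raw))], raw$Feature)
})

test_that("partial dependence matches direct row-by-row averaging", {
  m <- toy_model(60, n_trees = 15)
  grid <- seq(-2, 2, length.out = 7)
  pd <- partial_dependence(m, "x1", eval_grid = grid)
  expect_equal(pd$pd, oracle_partial_dependence(m, "x1", grid),
               tolerance = 1e-9)
  expect_equal(mean(pd$pd), 0, tolerance = 1e-12)
})

test_that("predictors the ensemble ignores give a flat centred curve", {
  tab <- separable_toy(100)
  tab$noise <- rnorm(100)
  # x1 separates perfectly; with 1 tree and 2 leaves only x1 is used
  m <- suppressWarnings(fit_niche(tab, hp = hyperparameters(
    n_trees = 1, max_nodes = 2, min_cases = 5, learning_rate = 1,
    subsample = 1), seed = 3))
  pd <- partial_dependence(m, "noise", eval_grid = seq(-2, 2, 0.5))
  expect_true(all(abs(pd$pd) < 1e-12))
})

test_that("a depth-1 tree's partial dependence is a step at its split", {
  tab <- separable_toy(100)
  m <- suppressWarnings(fit_niche(tab, hp = hyperparameters(
    n_trees = 1, max_nodes = 2, min_cases = 5, learning_rate = 1,
    subsample = 1), seed = 3))
  pd <- partial_dependence(m, "x1", eval_grid = seq(-2, 2, length.out = 41))
  vals <- unique(round(pd$pd, 10))
  expect_length(vals, 2)
  # the single jump brackets the tree's split point exactly
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = m$booster))
  split_at <- dt$Split[!is.na(dt$Split)][1]
  jump_at <- pd$value[which(diff(pd$pd) != 0)]
  expect_length(jump_at, 1)
  expect_lte(jump_at, split_at)
  expect_gt(jump_at + diff(pd$value[1:2]), split_at)
})

test_that("partial dependence is additive over single-variable ensembles", {
  # two models, each splitting on its own predictor; the Friedman average of
  # the summed latent predictor equals the sum of the individual curves
  set.seed(14)
  tab1 <- data.frame(label = rep(0:1, each = 30), x1 = c(rnorm(30, -1),
                                                         rnorm(30, 1)))
  tab1$x2 <- rnorm(60)
  tab2 <- tab1
  tab2$label <- as.integer(tab2$x1 > 0.5)
  hp <- suppressWarnings(
    hyperparameters(n_trees = 10, max_nodes = 2, min_cases = 5,
                    learning_rate = 0.5, subsample = 1))
  mA <- suppressWarnings(fit_niche(tab1, hp = hp, seed = 2))
  mB <- suppressWarnings(fit_niche(tab2, hp = hp, seed = 2))
  # same training rows, so the forced-value averages run over the same data
  mB$train_x <- mA$train_x
  grid <- seq(-2, 2, length.out = 9)
  pdA <- partial_dependence(mA, "x1", eval_grid = grid)
  pdB <- partial_dependence(mB, "x1", eval_grid = grid)
  sum_fun <- function(x) {
    predict(mA$booster, xgboost::xgb.DMatrix(x), outputmargin = TRUE) +
      predict(mB$booster, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
  }
  pd_sum <- vapply(grid, function(v) {
    x <- mA$train_x; x[, "x1"] <- v; mean(sum_fun(x))
  }, numeric(1))
  pd_sum <- pd_sum - mean(pd_sum)
  expect_equal(pdA$pd + pdB$pd, pd_sum, tolerance = 1e-9)
})

test_that("association ranges are the positive stretches of the curve", {
  all_pos <- structure(data.frame(value = 1:5, pd = rep(2, 5)),
                       class = c("pd_curve", "data.frame"))
  r1 <- extract_association_ranges(all_pos)
  expect_identical(c(r1$lo, r1$hi), c(1L, 5L))
  # step curve positive only from 70 up: one interval starting at 70
  vals <- seq(0, 100, by = 10)
  step <- structure(data.frame(value = vals, pd = ifelse(vals >= 70, 1, -1)),
                    class = c("pd_curve", "data.frame"))
  r2 <- extract_association_ranges(step)
  expect_identical(nrow(r2), 1L)
  expect_equal(r2$lo, 70)
  expect_equal(r2$hi, 100)
  # alternating signs across 4 segments: 2 intervals
  alt <- structure(data.frame(value = 1:8,
                              pd = rep(c(1, 1, -1, -1), 2)),
                   class = c("pd_curve", "data.frame"))
  r3 <- extract_association_ranges(alt)
  expect_identical(nrow(r3), 2L)
  # nowhere positive: empty
  neg <- structure(data.frame(value = 1:3, pd = c(-1, -2, -1)),
                   class = c("pd_curve", "data.frame"))
  expect_identical(nrow(extract_association_ranges(neg)), 0L)
})

test_that("class balancing is equivalent to duplicating the minority class", {
  set.seed(91)
  n1 <- 120; n0 <- 480
  mk <- function(n, mu) data.frame(x1 = rnorm(n, mu), x2 = rnorm(n))
  tab <- rbind(cbind(label = 1, mk(n1, 1.2)), cbind(label = 0, mk(n0, 0)))
  test <- rbind(cbind(label = 1, mk(200, 1.2)), cbind(label = 0, mk(200, 0)))
  hp_on <- suppressWarnings(
    hyperparameters(n_trees = 120, max_nodes = 6, min_cases = 10,
                    learning_rate = 0.05, class_balance = TRUE,
                    subsample = 1))
  hp_off <- suppressWarnings(
    hyperparameters(n_trees = 120, max_nodes = 6, min_cases = 10,
                    learning_rate = 0.05, class_balance = FALSE,
                    subsample = 1))
  m_bal <- suppressWarnings(fit_niche(tab, test, hp = hp_on, seed = 5))
  dup <- rbind(tab, do.call(rbind, rep(list(tab[tab$label == 1, ]), 3)))
  m_dup <- suppressWarnings(fit_niche(dup, test, hp = hp_off, seed = 5))
  expect_lt(abs(m_bal$report$auc - m_dup$report$auc), 0.02)
})

test_that("hyperparameter tuning picks the discriminating setting", {
  tab <- separable_toy(120, seed = 3)
  sp <- split_train_test(tab, 0.25, seed = 3)
  good <- suppressWarnings(
    hyperparameters(n_trees = 60, max_nodes = 4, min_cases = 5,
                    learning_rate = 0.3, subsample = 1))
  # min_cases >= class size: no split is ever admissible -> chance scores
  crippled <- suppressWarnings(
    hyperparameters(n_trees = 60, max_nodes = 4, min_cases = 50,
                    learning_rate = 0.3, subsample = 1))
  res <- suppressWarnings(
    tune_hyperparameters(sp$train, sp$test, list(crippled, good), seed = 3))
  expect_identical(res$best$hp$min_cases, 5L)
  expect_identical(nrow(res$tuning), 2L)
  # a single grid point returns that model; duplicates give identical rows
  one <- suppressWarnings(tune_hyperparameters(sp$train, sp$test,
                                               list(good), seed = 3))
  expect_identical(one$best$hp, good)
  two <- suppressWarnings(tune_hyperparameters(sp$train, sp$test,
                                               list(good, good), seed = 3))
  expect_equal(two$tuning[1, ], two$tuning[2, ], ignore_attr = TRUE)
  expect_error(tune_hyperparameters(sp$train, sp$test, list()), "empty")
})

test_that("out-of-range hyperparameters warn but are accepted", {
  expect_warning(hyperparameters(n_trees = 10), "1000-2000")
  expect_warning(hyperparameters(max_nodes = 2), "6-20")
  expect_warning(hyperparameters(min_cases = 1), "2-50")
  expect_silent(hyperparameters())
})

test_that("rows with missing predictors are excluded with a message", {
  tab <- separable_toy(100)
  tab$x2[c(3, 50)] <- NA
  expect_message(m <- suppressWarnings(fit_niche(tab, hp = hyperparameters(
    n_trees = 20, max_nodes = 4, min_cases = 5, learning_rate = 0.3),
    seed = 1)), "2 row")
  expect_identical(m$n_train, 98L)
})
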