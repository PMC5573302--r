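test_that("the F-measure worked examples are exact", {
  expect_equal(f_measure(list(TP = 10, FP = 0, FN = 0)), 1)
  expect_equal(f_measure(list(TP = 0, FP = 3, FN = 2)), 0)
  prec <- 8 / 10; rec <- 8 / 12
  expect_equal(f_measure(list(TP = 8, FP = 2, FN = 4)),
               2 * prec * rec / (prec + rec))
  expect_equal(f_measure(list(TP = 8, FP = 2, FN = 4)), 0.72727, tolerance = 1e-4)
})

test_that("sign discretization maps regression pairs to the right counts", {
  cc <- discretize_for_metrics(0.4, 0.7)
  expect_equal(cc[c("TP", "FP", "FN", "TN")], list(TP = 1L, FP = 0L, FN = 0L, TN = 0L),
               ignore_attr = TRUE)
  cc2 <- discretize_for_metrics(-0.1, 0.1)
  expect_identical(cc2$FN, 1L)
  cc3 <- discretize_for_metrics(c(0.5, -0.5, 0.5, -0.5),
                                c(0.5, -0.5, -0.5, 0.5))
  expect_equal(unlist(cc3), c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  # a perfect predictor always scores F = 1
  set.seed(11)
  q <- runif(50, -1, 1)
  expect_equal(f_measure(discretize_for_metrics(q, q)), 1)
  # k-bin agreement: exact pairs agree, off-bin pairs count as errors
  cb <- discretize_for_metrics(c(-0.9, 0.9), c(-0.9, 0.9), bins = 4)
  expect_identical(cb$FP, 0L)
  cb2 <- discretize_for_metrics(c(-0.9), c(0.9), bins = 4)
  expect_identical(cb2$FP, 1L)
})

test_that("non-dominated sorting and crowding follow their definitions", {
  FF <- rbind(c(1, 1), c(2, 0.5), c(0.5, 2), c(0.4, 0.4), c(2, 2))
  fronts <- fast_nondominated_sort(FF)
  expect_identical(sort(fronts[[1]]), 5L)         # (2,2) dominates all
  expect_identical(sort(fronts[[2]]), c(1L, 2L, 3L))
  expect_identical(sort(fronts[[3]]), 4L)
  cd <- crowding_distance(FF[fronts[[2]], ])
  expect_true(is.infinite(cd[2]) && is.infinite(cd[3]))  # boundary points
  expect_true(is.finite(cd[1]))
})

test_that("NSGA-II recovers the Pareto set of a toy bi-objective problem", {
  f <- function(x) c(-(x - 1)^2, -(x + 1)^2)
  oracle <- grid_pareto(f, -2, 2)
  res <- nsga2(function(x) f(x[1]), lower = -2, upper = 2,
               pop_size = 40, generations = 30, seed = 21)
  front_x <- res$X[res$front, 1]
  # the analytic Pareto set is x in [-1, 1]; the oracle grid confirms it
  expect_true(all(oracle$x >= -1 - 1e-6 & oracle$x <= 1 + 1e-6))
  expect_true(all(front_x >= -1.05 & front_x <= 1.05))
  expect_gt(length(unique(round(front_x, 2))), 5)  # spread along the front
  # per-generation properties: first front mutually non-dominated,
  # hypervolume non-decreasing up to crowding-truncation losses (the
  # diversity-preserving truncation may shed boundary area when the front
  # outgrows the population)
  ref <- c(-10, -10)
  hv <- numeric(length(res$history))
  for (g in seq_along(res$history)) {
    fr <- res$history[[g]]$front_F
    nd <- fast_nondominated_sort(fr)
    expect_identical(sort(nd[[1]]), seq_len(nrow(fr)))
    hv[g] <- hypervolume_2d(fr, ref)
  }
  expect_true(all(diff(hv) >= -0.02 * max(hv)))
  expect_gt(hv[length(hv)], hv[1] - 1e-9)
  # and the final hypervolume approaches the oracle's
  expect_gt(hv[length(hv)], 0.95 * hypervolume_2d(oracle$F, ref))
})

test_that("the hyperparameter search returns a mutually non-dominated front", {
  task <- synth_q_task(40, seed = 31)
  sr <- nsga2_search(task$window, "rbf",
                     default_config()$learning$svr_ranges,
                     pop = 6, generations = 2, seed = 5)
  FF <- as.matrix(sr$front[, c("recall", "precision", "f")])
  nd <- fast_nondominated_sort(FF)
  expect_identical(sort(nd[[1]]), seq_len(nrow(FF)))
  expect_true(all(c(sr$spec$C, sr$spec$gamma) > 0))
  expect_error(nsga2_search(new_experience_window(5, "x"), "rbf",
                            default_config()$learning$svr_ranges),
               "empty")
})

test_that("the fitted ensemble predicts well on a smooth noiseless target and is reproducible", {
  task <- synth_q_task(60, seed = 41, noise = 0)
  ens <- fit_ensemble(task$window, pop = 6, generations = 2, seed = 3,
                      action_levels = allowed_actions("cancerous"))
  expect_s3_class(ens, "svr_ensemble")
  expect_true(all(ens$weights >= 0) && any(ens$weights > 0))
  # held-out RMSE well below the response spread
  test_task <- synth_q_task(60, seed = 42, noise = 0)
  pred <- predict_q(ens, test_task$X, test_task$a)
  expect_lt(sqrt(mean((pred - test_task$y)^2)), sd(test_task$y))
  expect_true(all(pred >= -1 & pred <= 1))
  # identical window and seed: identical ensemble and predictions
  ens2 <- fit_ensemble(task$window, pop = 6, generations = 2, seed = 3,
                       action_levels = allowed_actions("cancerous"))
  expect_equal(predict_q(ens2, test_task$X, test_task$a), pred)
  # deterministic prediction
  expect_identical(predict_q(ens, test_task$X, test_task$a), pred)
})

test_that("a window of identical samples degenerates to a constant predictor", {
  vars <- state_vars_for("cancerous")
  w <- new_experience_window(20, vars)
  st <- setNames(rep(0.5, length(vars)), vars)
  for (k in 1:12) w <- admit_experience(w, st, "migration", 0.3, 1, 0)
  ens <- fit_ensemble(w, pop = 6, generations = 2, seed = 1,
                      action_levels = allowed_actions("cancerous"))
  p <- predict_q(ens, rbind(st, st * 2), c("migration", "necrosis"))
  expect_equal(p, c(0.3, 0.3), tolerance = 1e-6)
  expect_error(fit_ensemble(new_experience_window(20, vars), min_size = 10),
               "at least")
})

test_that("weighted voting and clipping behave as specified", {
  task <- synth_q_task(30, seed = 51)
  ens <- fit_ensemble(task$window, pop = 6, generations = 2, seed = 2,
                      action_levels = allowed_actions("cancerous"))
  X1 <- task$X[1, , drop = FALSE]
  a1 <- task$a[1]
  per_kernel <- vapply(ens$models,
                       function(m) oncolattice:::predict_svr(
                         m, oncolattice:::ensemble_features(ens, X1, a1)),
                       numeric(1))
  manual <- sum(ens$weights * per_kernel) / sum(ens$weights)
  expect_equal(predict_q(ens, X1, a1), min(max(manual, -1), 1))
  # one kernel carrying all weight reproduces that kernel
  ens1 <- ens
  ens1$weights <- c(rbf = 1, polynomial = 0, sigmoid = 0)
  expect_equal(predict_q(ens1, X1, a1),
               min(max(per_kernel[["rbf"]], -1), 1))
  ens0 <- ens
  ens0$weights[] <- 0
  expect_error(predict_q(ens0, X1, a1), "zero")
})

test_that("the ensemble is never worse than its worst member (MAPE, 20 tasks)", {
  worst_ok <- logical(20)
  for (rep in 1:20) {
    task <- synth_q_task(40, seed = 100 + rep, noise = 0.05)
    ens <- fit_ensemble(task$window, pop = 6, generations = 2,
                        seed = rep, action_levels = allowed_actions("cancerous"))
    test_task <- synth_q_task(40, seed = 500 + rep, noise = 0.05)
    Xf <- oncolattice:::ensemble_features(ens, test_task$X, test_task$a)
    mape <- function(pred) {
      nz <- test_task$y != 0
      mean(abs((pred[nz] - test_task$y[nz]) / test_task$y[nz])) * 100
    }
    kernel_mape <- vapply(ens$models,
                          function(m) mape(pmin(pmax(
                            oncolattice:::predict_svr(m, Xf), -1), 1)),
                          numeric(1))
    ens_mape <- mape(predict_q(ens, test_task$X, test_task$a))
    worst_ok[rep] <- ens_mape <= max(kernel_mape) + 1e-9
  }
  expect_true(all(worst_ok))
})

test_that("ensembles survive a save/load round trip", {
  task <- synth_q_task(30, seed = 61)
  ens <- fit_ensemble(task$window, pop = 6, generations = 2, seed = 4,
                      action_levels = allowed_actions("cancerous"))
  path <- withr::local_tempfile(fileext = ".rds")
  ensemble_save(ens, path)
  back <- ensemble_load(path)
  expect_equal(predict_q(back, task$X, task$a),
               predict_q(ens, task$X, task$a))
})
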