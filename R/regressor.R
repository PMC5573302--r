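#' F-measure from classification counts
#'
#' Harmonic mean of precision `TP / (TP + FP)` and recall `TP / (TP + FN)`.
#' When there are no true positives (or either denominator is zero) the
#' F-measure is defined as 0.
#'
#' @param counts list or named vector with `TP`, `FP`, `FN` (and optionally
#'   `TN`), all non-negative.
#' @return scalar in \[0, 1\].
#' @examples
#' f_measure(list(TP = 8, FP = 2, FN = 4))  # ~0.7273
#' @export
f_measure <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp == 0 || tp + fp == 0 || tp + fn == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * rec * prec / (rec + prec)
}

precision_recall <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  c(recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    f = f_measure(counts))
}

#' Classification counts for a regression pair set
#'
#' The learning labels are continuous Q values in \[-1, 1\], while the
#' kernel-voting weights are classification metrics; this maps regression
#' predictions onto classification counts. With the default `"sign"` rule
#' the positive class is `q >= 0` and counts are the usual binary TP/FP/
#' FN/TN. With `bins = k` the interval \[-1, 1\] is split into `k` equal
#' bins and counts are micro-averaged bin agreement: an agreeing pair is a
#' TP (or TN for the lowest bin), a disagreeing pair contributes one FP
#' (for the predicted bin) and one FN (for the true bin).
#'
#' @param q_pred,q_true numeric vectors in \[-1, 1\].
#' @param bins `"sign"` (default) or an integer number of bins `>= 2`.
#' @return list with `TP`, `FP`, `FN`, `TN`.
#' @export
discretize_for_metrics <- function(q_pred, q_true, bins = "sign") {
  stopifnot(length(q_pred) == length(q_true))
  if (identical(bins, "sign")) {
    pp <- q_pred >= 0; tp_ <- q_true >= 0
    return(list(TP = sum(pp & tp_), FP = sum(pp & !tp_),
                FN = sum(!pp & tp_), TN = sum(!pp & !tp_)))
  }
  k <- as.integer(bins)
  stopifnot(k >= 2L)
  cutb <- function(q) pmin(pmax(floor((q + 1) / 2 * k) + 1L, 1L), k)
  bp <- cutb(q_pred); bt <- cutb(q_true)
  agree <- bp == bt
  list(TP = sum(agree & bt > 1L), FP = sum(!agree), FN = sum(!agree),
       TN = sum(agree & bt == 1L))
}

svr_kernels <- c("rbf", "polynomial", "sigmoid")

map_kernel <- function(kernel) {
  switch(kernel, rbf = "radial", polynomial = "polynomial",
         sigmoid = "sigmoid",
         stop("unknown kernel family: ", kernel, call. = FALSE))
}

# Fit one SVR; degenerate windows (constant response, numerically singular
# problems) fall back to a constant predictor so the ensemble stays usable.
fit_svr <- function(X, y, kernel, C, epsilon, gamma) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  fit <- if (sd(y) > 0) {
    tryCatch(
      suppressWarnings(e1071::svm(Xs, y, type = "eps-regression",
                                  kernel = map_kernel(kernel), cost = C,
                                  epsilon = epsilon, gamma = gamma,
                                  scale = FALSE)),
      error = function(e) NULL)
  } else NULL
  structure(list(kernel = kernel, C = C, epsilon = epsilon, gamma = gamma,
                 fit = fit, const = mean(y), center = ctr, scale = scl),
            class = "oncosim_svr")
}

predict_svr <- function(model, X) {
  if (is.null(model$fit)) return(rep(model$const, nrow(X)))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.numeric(predict(model$fit, Xs))
}

# k-fold cross-validated (recall, precision, F) for one hyperparameter spec.
cv_objectives <- function(X, y, kernel, C, epsilon, gamma, folds = 3L,
                          bins = "sign") {
  n <- nrow(X)
  folds <- max(2L, min(folds, n))
  fold_id <- rep_len(seq_len(folds), n)
  counts <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) < 2L) next
    m <- fit_svr(X[tr, , drop = FALSE], y[tr], kernel, C, epsilon, gamma)
    pr <- predict_svr(m, X[!tr, , drop = FALSE])
    cc <- discretize_for_metrics(pr, y[!tr], bins)
    counts <- counts + unlist(cc)
  }
  precision_recall(as.list(counts))
}

window_features <- function(window, action_levels) {
  X <- window$state
  A <- outer(window$action, action_levels, `==`) * 1
  colnames(A) <- paste0("action_", action_levels)
  cbind(X, A)
}

#' NSGA-II hyperparameter search for one SVR kernel family
#'
#' Maximizes cross-validated (recall, precision, F-measure) over
#' `(C, epsilon, gamma)` — `C` and `gamma` searched on a log10 scale —
#' and returns the final non-dominated set. A single spec is extracted from
#' the front by highest F-measure, ties broken by crowding distance.
#'
#' @param window an [new_experience_window()] with training samples.
#' @param kernel `"rbf"`, `"polynomial"` or `"sigmoid"`.
#' @param ranges list with elements `C`, `epsilon`, `gamma`, each a
#'   `c(lo, hi)` pair.
#' @param pop,generations NSGA-II budget.
#' @param seed integer seed for the search stream.
#' @param action_levels action labels defining the one-hot feature layout.
#' @param folds CV folds for objective evaluation.
#' @return list with `front` (data.frame of specs and objectives) and
#'   `spec` (the chosen `C`, `epsilon`, `gamma`), plus the raw search
#'   result.
#' @export
nsga2_search <- function(window, kernel, ranges, pop = 8L, generations = 3L,
                         seed = 1L, action_levels = sort(unique(window$action)),
                         folds = 3L) {
  if (window_size(window) == 0L)
    stop("empty training window", call. = FALSE)
  X <- window_features(window, action_levels)
  y <- window$q
  lower <- c(log10(ranges$C[1]), ranges$epsilon[1], log10(ranges$gamma[1]))
  upper <- c(log10(ranges$C[2]), ranges$epsilon[2], log10(ranges$gamma[2]))
  decode <- function(x) list(C = 10^x[1], epsilon = x[2], gamma = 10^x[3])
  res <- nsga2(function(x) {
    s <- decode(x)
    cv_objectives(X, y, kernel, s$C, s$epsilon, s$gamma, folds)
  }, lower, upper, pop_size = pop, generations = generations, seed = seed)
  fr <- res$front
  FF <- res$F[fr, , drop = FALSE]
  colnames(FF) <- c("recall", "precision", "f")
  cd <- crowding_distance(FF)
  best <- fr[order(-FF[, "f"], -cd)[1]]
  specs <- t(apply(res$X[fr, , drop = FALSE], 1, function(x) unlist(decode(x))))
  list(front = data.frame(specs, FF),
       spec = decode(res$X[best, ]),
       search = res)
}

#' Fit the three-kernel SVR ensemble
#'
#' For each kernel family (RBF, polynomial, sigmoid): run the NSGA-II
#' hyperparameter search on the window, fit the selected spec on the full
#' window, and weight the kernel by its training F-measure (sign-agreement
#' discretization of Q by default). Refitting with the identical window and
#' seed reproduces the identical ensemble.
#'
#' @inheritParams nsga2_search
#' @param min_size minimum window size required (documented default 10).
#' @param bins discretization rule for the weight metric.
#' @return an `svr_ensemble` with per-kernel fits, weights, the feature
#'   layout, and a fingerprint of the training window.
#' @export
fit_ensemble <- function(window, ranges = default_config()$learning$svr_ranges,
                         pop = 8L, generations = 3L, seed = 1L,
                         action_levels = sort(unique(window$action)),
                         min_size = 10L, folds = 3L, bins = "sign") {
  n <- window_size(window)
  if (n < min_size)
    stop("training window has ", n, " samples; need at least ", min_size,
         call. = FALSE)
  X <- window_features(window, action_levels)
  y <- window$q
  models <- list()
  weights <- numeric(0)
  for (kern in svr_kernels) {
    sr <- nsga2_search(window, kern, ranges, pop, generations,
                       seed = stream_seed(seed, paste0("nsga_", kern)),
                       action_levels = action_levels, folds = folds)
    m <- fit_svr(X, y, kern, sr$spec$C, sr$spec$epsilon, sr$spec$gamma)
    w <- f_measure(discretize_for_metrics(predict_svr(m, X), y, bins))
    models[[kern]] <- m
    weights[kern] <- w
  }
  if (all(weights == 0)) weights[] <- 1  # uninformative window: plain average
  structure(list(models = models, weights = weights,
                 state_vars = window$state_vars,
                 action_levels = action_levels,
                 fingerprint = c(n = n, sum_q = sum(y)),
                 bins = bins),
            class = "svr_ensemble")
}

ensemble_features <- function(ensemble, states, actions) {
  if (is.null(dim(states)))
    states <- matrix(states, nrow = 1,
                     dimnames = list(NULL, names(states)))
  X <- states[, ensemble$state_vars, drop = FALSE]
  A <- outer(actions, ensemble$action_levels, `==`) * 1
  colnames(A) <- paste0("action_", ensemble$action_levels)
  cbind(X, A)
}

#' Predict Q for state-action pairs with the ensemble
#'
#' Weight-normalized average of the three kernel predictions, clipped to
#' \[-1, 1\]. Deterministic for a fitted ensemble.
#'
#' @param ensemble a fitted [fit_ensemble()] object.
#' @param states a named state vector, or a matrix of state rows.
#' @param actions action label(s), recycled against the state rows.
#' @return numeric Q predictions in \[-1, 1\].
#' @export
predict_q <- function(ensemble, states, actions) {
  if (all(ensemble$weights == 0)) stop("ensemble has all-zero weights",
                                       call. = FALSE)
  X <- ensemble_features(ensemble, states, actions)
  num <- numeric(nrow(X))
  for (kern in names(ensemble$models))
    num <- num + ensemble$weights[[kern]] * predict_svr(ensemble$models[[kern]], X)
  pmin(pmax(num / sum(ensemble$weights), -1), 1)
}

#' Save / load a fitted ensemble
#' @param ensemble a fitted ensemble.
#' @param path file path.
#' @return `path` / the restored ensemble.
#' @export
ensemble_save <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname ensemble_save
#' @export
ensemble_load <- function(path) {
  e <- readRDS(path)
  stopifnot(inherits(e, "svr_ensemble"))
  e
}

#' @export
print.svr_ensemble <- function(x, ...) {
  cat("<svr_ensemble>\n")
  for (kern in names(x$models)) {
    m <- x$models[[kern]]
    cat(sprintf("  %-10s C=%.3g eps=%.3g gamma=%.3g  weight=%.3f%s\n",
                kern, m$C, m$epsilon, m$gamma, x$weights[[kern]],
                if (is.null(m$fit)) " (constant fallback)" else ""))
  }
  invisible(x)
}
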