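# Bridges the optimizer to SVM training: zooming decoded solutions into
# (C, gamma), the stratified k-fold weighted-FNR/FPR fitness, final
# train/test evaluation, and the repeated-run comparison harnesses.

#' Zoom configuration mapping unit-interval solutions to (C, gamma)
#'
#' @param c_multiple zoom multiple `Cm` for the penalty factor; `C = Cm * S1`.
#' @param gamma_multiple zoom multiple `gm` for the RBF width;
#'   `gamma = gm * S2`. The defaults (1 and 2000) reflect a search over
#'   `C` in (0, 1] and `gamma` in (0, 2000].
#' @return An object of class `"zoom_config"`.
#' @export
zoom_config <- function(c_multiple = 1, gamma_multiple = 2000) {
  structure(
    list(
      c_multiple = check_positive(c_multiple, "c_multiple"),
      gamma_multiple = check_positive(gamma_multiple, "gamma_multiple")
    ),
    class = "zoom_config"
  )
}

#' Zoom a decoded solution into SVM parameters
#'
#' `C = Cm * S1` and `gamma = gm * S2`. Each parameter is clamped below at
#' `1e-6` times its multiple, because `C = 0` or `gamma = 0` is outside
#' the SVM contract and the solution boundary `S = 0` is reachable.
#'
#' @param solution numeric vector of length 2 with entries in `[0, 1]`.
#' @param zoom a [zoom_config()].
#' @return A list with positive `c` and `gamma`.
#' @examples
#' zoom_parameters(c(0.5, 0.5), zoom_config())  # C = 0.5, gamma = 1000
#' @export
zoom_parameters <- function(solution, zoom = zoom_config()) {
  stopifnot(inherits(zoom, "zoom_config"))
  solution <- as.numeric(solution)
  if (length(solution) != 2L || anyNA(solution) ||
      any(solution < 0 | solution > 1)) {
    stopf("`solution` must be two numbers in [0, 1]")
  }
  list(
    c = max(zoom$c_multiple * solution[1], 1e-6 * zoom$c_multiple),
    gamma = max(zoom$gamma_multiple * solution[2], 1e-6 * zoom$gamma_multiple)
  )
}

#' Construct a labeled feature dataset
#'
#' @param features numeric matrix (samples in rows).
#' @param labels vector over \{+1, -1\}, one per row.
#' @return An object of class `"svm_dataset"`.
#' @export
svm_dataset <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(as.character(labels))
  if (nrow(features) != length(labels)) {
    stopf("row count of `features` (%d) must equal label count (%d)",
          nrow(features), length(labels))
  }
  if (!all(labels %in% c(-1, 1))) stopf("labels must lie in {+1, -1}")
  if (anyNA(features)) stopf("`features` must not contain NA")
  structure(list(features = features, labels = labels), class = "svm_dataset")
}

#' @export
print.svm_dataset <- function(x, ...) {
  cat(sprintf("<svm_dataset: %d samples x %d features; %d positive, %d negative>\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}

#' Read a dataset from delimited text
#'
#' Expects a header, one label column holding +1/-1, and numeric feature
#' columns.
#'
#' @param path CSV file path.
#' @param label_col name of the label column (default `"label"`).
#' @param sep field separator.
#' @return An [svm_dataset()].
#' @export
read_dataset_csv <- function(path, label_col = "label", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!label_col %in% names(df)) {
    stopf("label column `%s` not found in %s (columns: %s)",
          label_col, path, paste(names(df), collapse = ", "))
  }
  labels <- df[[label_col]]
  feats <- df[setdiff(names(df), label_col)]
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    stopf("all feature columns in %s must be numeric", path)
  }
  svm_dataset(as.matrix(feats), labels)
}

#' Write a dataset as delimited text
#'
#' @param data an [svm_dataset()].
#' @param path output CSV path.
#' @param label_col name for the label column.
#' @return Invisibly, `path`.
#' @export
write_dataset_csv <- function(data, path, label_col = "label") {
  stopifnot(inherits(data, "svm_dataset"))
  feats <- as.data.frame(data$features)
  if (is.null(colnames(data$features))) {
    names(feats) <- sprintf("f%02d", seq_len(ncol(feats)))
  }
  df <- cbind(feats, stats::setNames(data.frame(data$labels), label_col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic stratified fold assignment
#'
#' Shuffles each class separately under `fold_seed` and deals its members
#' round-robin over the K folds, so every fold contains both classes
#' whenever each class has at least K members.
#'
#' @param labels vector over \{+1, -1\}.
#' @param k number of folds.
#' @param fold_seed integer seed fixing the assignment.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k, fold_seed) {
  k <- check_count(k, "k", min = 2L)
  labels <- as.numeric(as.character(labels))
  if (!all(labels %in% c(-1, 1))) stopf("labels must lie in {+1, -1}")
  for (cls in c(1, -1)) {
    if (sum(labels == cls) < k) {
      stopf("class %+d has %d samples; need at least k = %d for stratified folds",
            cls, sum(labels == cls), k)
    }
  }
  folds <- integer(length(labels))
  with_seed(fold_seed, {
    for (cls in c(1, -1)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Standardize train columns to zero mean / unit variance and apply the same
# transform to test columns; constant columns are left centred only.
standardize_fit_apply <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sd <- apply(train_x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(
    train = sweep(sweep(train_x, 2, mu), 2, sd, `/`),
    test = sweep(sweep(test_x, 2, mu), 2, sd, `/`)
  )
}

svm_fit_predict <- function(train_x, train_y, test_x, params) {
  std <- standardize_fit_apply(train_x, test_x)
  fit <- e1071::svm(std$train, factor(train_y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = params$c, gamma = params$gamma, scale = FALSE)
  as.numeric(as.character(stats::predict(fit, std$test)))
}

#' Cross-validated weighted fitness of one SVM candidate
#'
#' Splits the training set into K stratified folds (deterministically per
#' `fold_seed`), trains an RBF-kernel soft-margin SVM at `(C, gamma)` on
#' each K-1-fold union, records (FNR, FPR) on the held-out fold, and
#' returns the [weighted_cv_fitness()] of the K pairs. Feature
#' standardization is fitted on the training folds only. Fold assignment
#' depends only on the labels and `fold_seed`, so fitness comparisons
#' between candidates within one optimization run are like-for-like.
#'
#' @param train an [svm_dataset()]; each class needs at least `k_folds`
#'   members.
#' @param params list with `c` and `gamma` (see [zoom_parameters()]).
#' @param fitcfg a [fitness_config()].
#' @param fold_seed integer seed fixing the fold split.
#' @return The fitness, a number in `[0, 1]`; smaller is better.
#' @export
evaluate_candidate <- function(train, params, fitcfg = fitness_config(),
                               fold_seed = 1L) {
  stopifnot(inherits(train, "svm_dataset"), inherits(fitcfg, "fitness_config"))
  folds <- stratified_folds(train$labels, fitcfg$k_folds, fold_seed)
  rates <- lapply(seq_len(fitcfg$k_folds), function(k) {
    hold <- folds == k
    pred <- svm_fit_predict(train$features[!hold, , drop = FALSE],
                            train$labels[!hold],
                            train$features[hold, , drop = FALSE], params)
    m <- rates_from_confusion(
      confusion_from_predictions(train$labels[hold], pred)
    )
    data.frame(fnr = m$fnr, fpr = m$fpr)
  })
  weighted_cv_fitness(do.call(rbind, rates), fitcfg$fnr_weight)
}

#' Tune an RBF-SVM with a fruit fly optimizer and evaluate on a test set
#'
#' Composes the optimizer over the objective
#' `solution -> evaluate_candidate(train, zoom_parameters(solution, zoom),
#' fitcfg, fold_seed)`, with `fold_seed` taken from `optcfg$seed` so the
#' fold split is frozen across all candidate evaluations of the run. After
#' optimization the final SVM is trained on the full training set at the
#' best parameters and scored on `test`.
#'
#' @param train,test [svm_dataset()] objects with matching feature
#'   dimensionality.
#' @param optcfg an [optimizer_config()] (its `dimension` must be 2).
#' @param fitcfg a [fitness_config()].
#' @param zoom a [zoom_config()].
#' @param method `"qfoa"` (default), `"foa"`, or `"grid"` (exhaustive
#'   reference search over a `grid_points` x `grid_points` lattice of
#'   solutions in (0, 1]^2).
#' @param grid_points lattice side length for `method = "grid"`.
#' @return An object of class `"tuning_result"`: list with `best_params`
#'   (`c`, `gamma`), `best_fitness`, `best_solution`, `trajectory`,
#'   `test_metrics` (a `classification_metrics`), `fold_seed`, `seed`,
#'   `method`, `evaluations`.
#' @export
tune_svm <- function(train, test, optcfg = optimizer_config(),
                     fitcfg = fitness_config(), zoom = zoom_config(),
                     method = c("qfoa", "foa", "grid"), grid_points = 20L) {
  stopifnot(inherits(train, "svm_dataset"), inherits(test, "svm_dataset"))
  method <- match.arg(method)
  if (ncol(train$features) != ncol(test$features)) {
    stopf("train and test feature dimensionality differ (%d vs %d)",
          ncol(train$features), ncol(test$features))
  }
  if (optcfg$dimension != 2L) {
    stopf("SVM tuning optimizes (C, gamma); `optcfg$dimension` must be 2")
  }
  fold_seed <- optcfg$seed
  objective <- function(solution) {
    evaluate_candidate(train, zoom_parameters(solution, zoom), fitcfg,
                       fold_seed)
  }
  opt <- switch(
    method,
    qfoa = qfoa_optimize(objective, optcfg),
    foa = foa_optimize(objective, optcfg, sense = "min"),
    grid = grid_optimize(objective, grid_points, optcfg$seed)
  )
  best_params <- zoom_parameters(opt$best_solution, zoom)
  pred <- svm_fit_predict(train$features, train$labels, test$features,
                          best_params)
  structure(
    list(
      best_params = best_params,
      best_fitness = opt$best_fitness,
      best_solution = opt$best_solution,
      trajectory = opt$best_fitness_per_iteration,
      test_metrics = rates_from_confusion(
        confusion_from_predictions(test$labels, pred)
      ),
      fold_seed = fold_seed,
      seed = optcfg$seed,
      method = method,
      evaluations = opt$evaluations
    ),
    class = "tuning_result"
  )
}

# Exhaustive lattice reference: solutions (i/g, j/g), i,j in 1..g. No
# randomness; `seed` is recorded for interface symmetry only.
grid_optimize <- function(objective, grid_points, seed) {
  g <- check_count(grid_points, "grid_points", min = 2L)
  vals <- seq_len(g) / g
  best <- Inf
  best_sol <- NULL
  traj <- numeric(0)
  for (s1 in vals) {
    for (s2 in vals) {
      f <- objective(c(s1, s2))
      if (f < best) {
        best <- f
        best_sol <- c(s1, s2)
      }
      traj <- c(traj, best)
    }
  }
  structure(
    list(
      best_fitness = best,
      best_solution = best_sol,
      best_position = NULL,
      best_fitness_per_iteration = traj,
      evaluations = g * g,
      seed = seed,
      method = "grid"
    ),
    class = "optimization_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result (%s): C %.6g, gamma %.6g, CV fitness %.6g>\n",
              x$method, x$best_params$c, x$best_params$gamma, x$best_fitness))
  cat("test: ")
  print(x$test_metrics)
  invisible(x)
}

tuning_runs_df <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    m <- r$test_metrics
    data.frame(
      C = r$best_params$c, gamma = r$best_params$gamma,
      FPR = m$fpr, FNR = m$fnr, Accuracy = m$accuracy,
      Precision = ifelse(is.na(m$precision), 0, m$precision), F1 = m$f1,
      fitness = r$best_fitness, seed = r$seed
    )
  }))
}

summary_rows <- function(df, cols) {
  out <- lapply(cols, function(cc) {
    s <- summarize_runs(df[[cc]])
    data.frame(stat = c("mean", "sample_std"), column = cc,
               value = c(s$mean, s$sample_std))
  })
  do.call(rbind, out)
}

#' Repeated tuning runs over a grid of FNR weights
#'
#' For each weight `w`, runs [tune_svm()] `repeats` times with seeds
#' `base_seed, base_seed + 1, ...` and summarizes C, gamma, FPR, FNR,
#' Accuracy, Precision and F1 with mean and sample standard deviation.
#' This is the protocol for choosing the missed-diagnosis weight: heavier
#' `w` trades false alarms for fewer missed diagnoses.
#'
#' @param train,test [svm_dataset()] objects.
#' @param weights numeric vector of FNR weights, each in `[0.5, 1]`.
#' @param repeats runs per weight (>= 2).
#' @param base_seed first seed.
#' @param optcfg,fitcfg,zoom configuration objects; `fitcfg$fnr_weight`
#'   is overridden by each `w`.
#' @return A list with `summary` (data frame: w, column, mean,
#'   sample_std) and `runs` (per-run data frame with a `w` column).
#' @export
run_weight_sweep <- function(train, test, weights = seq(0.5, 1, by = 0.1),
                             repeats = 10L, base_seed = 1L,
                             optcfg = optimizer_config(),
                             fitcfg = fitness_config(), zoom = zoom_config()) {
  weights <- as.numeric(weights)
  if (any(weights < 0.5 | weights > 1)) {
    stopf("FNR weights must lie in [0.5, 1]")
  }
  repeats <- check_count(repeats, "repeats", min = 2L)
  cols <- c("C", "gamma", "FPR", "FNR", "Accuracy", "Precision", "F1")
  all_runs <- list()
  all_sum <- list()
  for (w in weights) {
    fc <- fitness_config(fitcfg$k_folds, w)
    res <- lapply(seq_len(repeats) - 1L, function(i) {
      oc <- optcfg
      oc$seed <- base_seed + i
      tune_svm(train, test, oc, fc, zoom)
    })
    df <- tuning_runs_df(res)
    df$w <- w
    all_runs[[length(all_runs) + 1L]] <- df
    sm <- lapply(cols, function(cc) {
      s <- summarize_runs(df[[cc]])
      data.frame(w = w, column = cc, mean = s$mean, sample_std = s$sample_std)
    })
    all_sum[[length(all_sum) + 1L]] <- do.call(rbind, sm)
  }
  list(summary = do.call(rbind, all_sum), runs = do.call(rbind, all_runs))
}

#' Repeated-run comparison of tuning methods
#'
#' Runs each requested method `repeats` times (seeds `base_seed`,
#' `base_seed + 1`, ...) and reports the mean and sample standard
#' deviation of FPR, FNR, Accuracy, Precision, F1, C and gamma per method.
#' `"grid"` is the deterministic exhaustive reference, so its spread
#' across repeats is zero.
#'
#' @param train,test [svm_dataset()] objects.
#' @param methods non-empty subset of `c("qfoa", "foa", "grid")`.
#' @param repeats runs per method.
#' @param base_seed first seed.
#' @param optcfg,fitcfg,zoom configuration objects.
#' @param grid_points lattice side for the grid reference.
#' @return A list with `summary` (data frame: method, column, mean,
#'   sample_std) and `runs` (per-run data frame with a `method` column).
#' @export
compare_optimizers <- function(train, test,
                               methods = c("qfoa", "foa", "grid"),
                               repeats = 10L, base_seed = 1L,
                               optcfg = optimizer_config(),
                               fitcfg = fitness_config(),
                               zoom = zoom_config(), grid_points = 20L) {
  methods <- match.arg(methods, c("qfoa", "foa", "grid"), several.ok = TRUE)
  repeats <- check_count(repeats, "repeats", min = 1L)
  cols <- c("C", "gamma", "FPR", "FNR", "Accuracy", "Precision", "F1",
            "fitness")
  all_runs <- list()
  all_sum <- list()
  for (m in methods) {
    res <- lapply(seq_len(repeats) - 1L, function(i) {
      oc <- optcfg
      oc$seed <- base_seed + i
      tune_svm(train, test, oc, fitcfg, zoom, method = m,
               grid_points = grid_points)
    })
    df <- tuning_runs_df(res)
    df$method <- m
    all_runs[[length(all_runs) + 1L]] <- df
    sm <- lapply(cols, function(cc) {
      s <- summarize_runs(df[[cc]])
      data.frame(method = m, column = cc, mean = s$mean,
                 sample_std = s$sample_std)
    })
    all_sum[[length(all_sum) + 1L]] <- do.call(rbind, sm)
  }
  list(summary = do.call(rbind, all_sum), runs = do.call(rbind, all_runs))
}
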