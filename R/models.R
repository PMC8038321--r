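#' Train a random forest classifier
#'
#' Bootstrap-sampled decision trees (ranger backend) with feature subsampling
#' of `ceiling(sqrt(p))` per split; the continuous positive-class score is the
#' fraction of trees voting positive, so thresholding the score at 0.5
#' reproduces the majority vote. Deterministic given `seed`.
#'
#' @param x feature matrix (samples x features).
#' @param y binary labels (0/1 vector).
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth; `NULL` or 0 for unlimited.
#' @param min_node_size minimum node size (the exposed "cost of division").
#' @param seed integer seed (controls bootstrap and feature subsampling).
#' @return An `ehg_model` of kind `"rf"`.
#' @export
train_rf <- function(x, y, n_trees = 500, max_depth = NULL, min_node_size = 1,
                     seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("training data contain a single class")
  if (!is.null(max_depth) && max_depth == 0) max_depth <- NULL
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- ranger::ranger(
    x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
    num.trees = n_trees, max.depth = max_depth, min.node.size = min_node_size,
    mtry = ceiling(sqrt(ncol(x))), probability = TRUE, seed = seed,
    num.threads = 1, verbose = FALSE)
  structure(list(kind = "rf", fit = fit,
                 hyperparameters = list(n_trees = n_trees, max_depth = max_depth,
                                        min_node_size = min_node_size, seed = seed)),
            class = "ehg_model")
}

elm_activation <- function(name) {
  switch(name,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         tanh = tanh,
         relu = function(z) pmax(z, 0),
         identity = identity,
         stop("unknown activation: ", name))
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer feedforward network: input weights and biases drawn
#' uniform(-1, 1) from `seed` and frozen; the hidden activations
#' `H = act(X W + b)` are mapped to the +/-1 class targets by the
#' Moore-Penrose pseudoinverse, `beta = pinv(H) t`. The raw network output is
#' rescaled to `(raw + 1) / 2` so the 0.5 score threshold reproduces the sign
#' rule.
#'
#' @param x feature matrix.
#' @param y binary labels (0/1).
#' @param n_hidden number of hidden neurons (>= 1).
#' @param activation one of `"sigmoid"`, `"tanh"`, `"relu"`, `"identity"`.
#' @param seed integer seed for the random input layer.
#' @return An `ehg_model` of kind `"elm"`.
#' @export
train_elm <- function(x, y, n_hidden, activation = "sigmoid", seed = 1L) {
  if (n_hidden < 1) stop("`n_hidden` must be at least 1")
  x <- as.matrix(x)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  p <- ncol(x)
  W <- matrix(stats::runif(p * n_hidden, -1, 1), p, n_hidden)
  b <- stats::runif(n_hidden, -1, 1)
  act <- elm_activation(activation)
  H <- act(x %*% W + matrix(b, nrow(x), n_hidden, byrow = TRUE))
  t_target <- ifelse(y == 1, 1, -1)
  beta <- MASS::ginv(H) %*% t_target
  structure(list(kind = "elm", W = W, b = b, beta = beta, activation = activation,
                 hyperparameters = list(n_hidden = n_hidden,
                                        activation = activation, seed = seed)),
            class = "ehg_model")
}

knn_kernel <- function(name) {
  switch(name,
         rectangular = function(d, k) rep(1, length(d)),
         triangular = function(d, k) pmax(1 - d, 0),
         epanechnikov = function(d, k) pmax(0.75 * (1 - d^2), 0),
         gaussian = function(d, k) exp(-0.5 * d^2),
         rank = function(d, k) (k + 1) - rank(d, ties.method = "first"),
         stop("unknown kernel: ", name))
}

#' Train (store) a weighted k-nearest-neighbor classifier
#'
#' Stores the training set; prediction scores a query by the kernel-weighted
#' positive fraction among its `k` nearest neighbors under the Minkowski
#' distance of order `minkowski_p`, with distances normalized by the
#' (k+1)-th neighbor distance before kernel weighting. Training involves no
#' randomness.
#'
#' @param x feature matrix.
#' @param y binary labels (0/1).
#' @param k number of neighbors (at most `nrow(x) - 1`).
#' @param minkowski_p Minkowski order (1 = Manhattan, 2 = Euclidean).
#' @param kernel one of `"rectangular"`, `"triangular"`, `"epanechnikov"`,
#'   `"gaussian"`, `"rank"`.
#' @return An `ehg_model` of kind `"knn"`.
#' @export
train_knn <- function(x, y, k, minkowski_p = 2, kernel = "rectangular") {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k = ", k, " exceeds the training size ", nrow(x))
  structure(list(kind = "knn", x = x, y = y,
                 hyperparameters = list(k = k, minkowski_p = minkowski_p,
                                        kernel = kernel)),
            class = "ehg_model")
}

#' Continuous positive-class score of a trained model
#'
#' All three model kinds return a score for which the 0.5 threshold reproduces
#' the model's discrete class output (tree vote fraction for RF, rescaled
#' network output for ELM, kernel-weighted neighbor fraction for KNN).
#'
#' @param model an `ehg_model`.
#' @param x feature matrix of queries.
#' @return Numeric score vector.
#' @export
predict_score <- function(model, x) {
  x <- as.matrix(x)
  if (model$kind == "rf") {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    pr <- stats::predict(model$fit, data = as.data.frame(x))$predictions
    return(pr[, "1"])
  }
  if (model$kind == "elm") {
    act <- elm_activation(model$activation)
    H <- act(x %*% model$W + matrix(model$b, nrow(x), length(model$b), byrow = TRUE))
    raw <- as.numeric(H %*% model$beta)
    return((raw + 1) / 2)
  }
  # knn
  hp <- model$hyperparameters
  kf <- knn_kernel(hp$kernel)
  p <- hp$minkowski_p
  k <- hp$k
  apply(x, 1, function(q) {
    d <- (rowSums(abs(sweep(model$x, 2, q))^p))^(1 / p)
    o <- order(d)
    dk <- d[o[seq_len(k)]]
    dnorm_ref <- if (k < length(d)) d[o[k + 1]] else max(dk)
    dn <- if (dnorm_ref > 0) dk / dnorm_ref else rep(0, k)
    w <- kf(dn, k)
    yk <- model$y[o[seq_len(k)]]
    if (sum(w) <= 0) mean(yk == 1) else sum(w * (yk == 1)) / sum(w)
  })
}

#' Discrete class prediction (score thresholded at 0.5)
#' @inheritParams predict_score
#' @return Integer vector of 0/1 labels.
#' @export
predict_class <- function(model, x) as.integer(predict_score(model, x) >= 0.5)

train_model <- function(kind, x, y, hp, seed = 1L) {
  switch(kind,
         rf = train_rf(x, y, hp$n_trees, hp$max_depth, hp$min_node_size, seed),
         elm = train_elm(x, y, hp$n_hidden, hp$activation, seed),
         knn = train_knn(x, y, hp$k, hp$minkowski_p, hp$kernel),
         stop("unknown classifier kind: ", kind))
}

#' Default hyperparameter grids
#'
#' @param kind `"rf"`, `"elm"` or `"knn"`.
#' @return Named list of hyperparameter value vectors.
#' @export
default_grid <- function(kind) {
  switch(kind,
         rf = list(n_trees = c(100, 250, 500), max_depth = c(4, 8, 16, 0),
                   min_node_size = c(1, 5, 10)),
         elm = list(n_hidden = c(10, 25, 50, 100, 150),
                    activation = c("sigmoid", "tanh", "relu")),
         knn = list(k = c(3, 5, 7, 9, 11, 13, 15), minkowski_p = c(1, 2),
                    kernel = c("rectangular", "triangular", "epanechnikov",
                               "gaussian", "rank")),
         stop("unknown classifier kind: ", kind))
}

#' Grid search with seed-as-hyperparameter over the design partitions
#'
#' For every hyperparameter combination and every partition, RF and ELM models
#' are trained with `n_seeds` candidate seeds; the seed with the best
#' validation F1-score is stored before any test evaluation (the seed ledger),
#' making stochastic training reproducible. KNN involves no training
#' randomness and is fitted once. Validation metrics at the stored seed are
#' averaged over partitions for both rankings, so both optimization criteria
#' consume identical partitions and seeds.
#'
#' @param design an `ehg_design` from [prepare_design()].
#' @param kind classifier kind.
#' @param grid named list of hyperparameter vectors (default
#'   [default_grid()]).
#' @param n_seeds candidate seeds per combination and partition (default 30).
#' @param seed_base first candidate seed; candidates are
#'   `seed_base + 0:(n_seeds-1)`.
#' @return An `ehg_search`: `combos` (data frame), `mean_f1`, `mean_sens`
#'   (per combo), `seeds` (combos x partitions matrix), `val_metrics` (list of
#'   per-partition metric data frames per combo).
#' @export
grid_search <- function(design, kind, grid = default_grid(kind), n_seeds = 30,
                        seed_base = 1000L) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  attr(combos, "out.attrs") <- NULL
  n_combo <- nrow(combos)
  n_part <- length(design$folds)
  stochastic <- kind %in% c("rf", "elm")
  seeds_used <- matrix(NA_integer_, n_combo, n_part)
  val_metrics <- vector("list", n_combo)
  for (ci in seq_len(n_combo)) {
    hp <- as.list(combos[ci, , drop = FALSE])
    pm <- matrix(NA_real_, n_part, 3,
                 dimnames = list(NULL, c("f1", "sensitivity", "specificity")))
    for (pi in seq_len(n_part)) {
      fold <- design$folds[[pi]]
      if (stochastic) {
        best <- NULL
        for (s in seed_base + 0:(n_seeds - 1)) {
          mdl <- train_model(kind, fold$xtr, fold$ytr, hp, s)
          met <- classification_metrics(
            confusion_counts(predict_class(mdl, fold$xval), fold$yval))
          f1 <- if (is.na(met["f1"])) -Inf else met["f1"]
          if (is.null(best) || f1 > best$f1) best <- list(f1 = f1, seed = s, met = met)
        }
        seeds_used[ci, pi] <- best$seed
        pm[pi, ] <- best$met
      } else {
        mdl <- train_model(kind, fold$xtr, fold$ytr, hp)
        pm[pi, ] <- classification_metrics(
          confusion_counts(predict_class(mdl, fold$xval), fold$yval))
      }
    }
    val_metrics[[ci]] <- as.data.frame(pm)
  }
  structure(list(kind = kind, combos = combos,
                 mean_f1 = vapply(val_metrics, function(m) mean(m$f1, na.rm = TRUE), numeric(1)),
                 mean_sens = vapply(val_metrics, function(m) mean(m$sensitivity, na.rm = TRUE), numeric(1)),
                 seeds = seeds_used, val_metrics = val_metrics),
            class = "ehg_search")
}

#' Select the optimal hyperparameter combination under a criterion
#'
#' Criterion `"f1"` maximizes the mean validation F1-score over partitions;
#' criterion `"sensitivity"` maximizes the mean validation sensitivity, with
#' ties (within 1e-9) broken by mean F1-score.
#'
#' @param search an `ehg_search` from [grid_search()].
#' @param criterion `"f1"` or `"sensitivity"`.
#' @return An `ehg_selection`: `kind`, `criterion`, `combo` (named list),
#'   `combo_index`, `seeds` (stored per-partition seeds), `val_metrics`
#'   (per-partition validation metrics at the stored seeds).
#' @export
select_model <- function(search, criterion = c("f1", "sensitivity")) {
  criterion <- match.arg(criterion)
  if (criterion == "f1") {
    best <- which.max(search$mean_f1)
  } else {
    s <- search$mean_sens
    top <- which(s >= max(s, na.rm = TRUE) - 1e-9)
    best <- top[which.max(search$mean_f1[top])]
  }
  structure(list(kind = search$kind, criterion = criterion,
                 combo = as.list(search$combos[best, , drop = FALSE]),
                 combo_index = best,
                 seeds = search$seeds[best, ],
                 val_metrics = search$val_metrics[[best]]),
            class = "ehg_selection")
}

#' Evaluate a selected model on every partition
#'
#' Retrains the selected combination on each partition's training subset with
#' its stored seed and computes metrics (and scores, for ROC analysis) on the
#' requested subset. Selection consumed only train/validation data, so this is
#' the first time test subsets are touched.
#'
#' @param design the `ehg_design` the selection was made on.
#' @param selection an `ehg_selection`.
#' @param subset `"test"`, `"validation"` or `"train"`.
#' @return List with `metrics` (per-partition data frame), and `scores`,
#'   `labels` (per-partition lists for ROC averaging).
#' @export
evaluate_selected <- function(design, selection,
                              subset = c("test", "validation", "train")) {
  subset <- match.arg(subset)
  n_part <- length(design$folds)
  pm <- matrix(NA_real_, n_part, 3,
               dimnames = list(NULL, c("f1", "sensitivity", "specificity")))
  scores <- labels <- vector("list", n_part)
  for (pi in seq_len(n_part)) {
    fold <- design$folds[[pi]]
    seed <- selection$seeds[pi]
    if (is.na(seed)) seed <- 1L
    mdl <- train_model(selection$kind, fold$xtr, fold$ytr, selection$combo, seed)
    xs <- switch(subset, test = fold$xte, validation = fold$xval, train = fold$xtr)
    ys <- switch(subset, test = fold$yte, validation = fold$yval, train = fold$ytr)
    sc <- predict_score(mdl, xs)
    pm[pi, ] <- classification_metrics(confusion_counts(as.integer(sc >= 0.5), ys))
    scores[[pi]] <- sc
    labels[[pi]] <- ys
  }
  list(metrics = as.data.frame(pm), scores = scores, labels = labels)
}
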