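#' SMOTE oversampling of the minority class
#'
#' Grows the minority class to `ratio` times its original count. Each synthetic
#' sample interpolates uniformly between a minority sample and one of its `k`
#' nearest minority neighbors; neighbor distances are Euclidean on z-scored
#' features so covariates on different scales are commensurate. Parents are
#' cycled evenly (each minority sample contributes `floor(ratio) - 1` synthetic
#' offspring, the remainder assigned at random). Interpolation happens in the
#' original feature space; synthetic rows are flagged
#' `origin = "synthetic_smote"`. The majority class is untouched.
#'
#' @param table an `ehg_table` from [build_table()].
#' @param ratio target minority size as a multiple of the original (default 3,
#'   i.e. 3:1). `ratio = 1` returns the table unchanged.
#' @param k number of minority neighbors to interpolate from (default 5).
#' @param seed integer seed.
#' @return The augmented `ehg_table`.
#' @export
smote <- function(table, ratio = 3, k = 5, seed = 1L) {
  stopifnot(inherits(table, "ehg_table"))
  if (ratio < 1) stop("`ratio` must be at least 1")
  if (ratio == 1) return(table)
  fn <- attr(table, "feature_names")
  counts <- table(factor(table$label, levels = c(0, 1)))
  minority_label <- as.integer(names(counts)[which.min(counts)])
  mi <- which(table$label == minority_label)
  n_min <- length(mi)
  if (n_min <= k)
    stop("minority class has ", n_min, " samples; needs more than k = ", k,
         " -- use a smaller k")
  X <- as.matrix(table[mi, fn])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[1:k]))

  n_new <- round((ratio - 1) * n_min)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  per <- rep(n_new %/% n_min, n_min)
  rem <- n_new %% n_min
  if (rem > 0) {
    extra <- sample.int(n_min, rem)
    per[extra] <- per[extra] + 1
  }
  new_rows <- vector("list", n_new)
  idx <- 1
  for (i in seq_len(n_min)) {
    for (j in seq_len(per[i])) {
      nb <- nn[i, sample.int(k, 1)]
      u <- stats::runif(1)
      feat <- X[i, ] + u * (X[nb, ] - X[i, ])
      row <- table[mi[i], , drop = FALSE]
      row[1, fn] <- as.list(feat)
      row$id <- sprintf("smote%03d", idx)
      row$origin <- "synthetic_smote"
      new_rows[[idx]] <- row
      idx <- idx + 1
    }
  }
  out <- rbind(table, do.call(rbind, new_rows))
  rownames(out) <- NULL
  attr(out, "feature_names") <- fn
  attr(out, "input_set") <- attr(table, "input_set")
  class(out) <- class(table)
  out
}

#' Build the repeated stratified holdout partitions
#'
#' For each of `n_reps` repetitions the sample indices are split into test
#' (`floor(N/3)`), training (`floor((N - test) * 2/3)`) and validation (the
#' remainder), i.e. 1/3 for test and, of the design two-thirds, 2/3 training
#' and 1/3 validation. Allocation is stratified by class with largest-remainder
#' rounding, so each subset's class proportions match the global ones within
#' one sample. The same partitions are reused across all classifiers and both
#' optimization criteria.
#'
#' @param table an `ehg_table` (only its `label` column is used).
#' @param n_reps number of repetitions (default 30).
#' @param seed integer seed.
#' @return List of class `ehg_partitions`: `n_reps` elements, each with
#'   integer index vectors `train`, `validation`, `test`.
#' @export
make_partitions <- function(table, n_reps = 30, seed = 1L) {
  y <- table$label
  N <- length(y)
  if (min(table(y)) < 3) stop("each class needs at least 3 samples")
  n_test <- floor(N / 3)
  n_train <- floor((N - n_test) * 2 / 3)
  n_val <- N - n_test - n_train

  # per-class largest-remainder allocation to the three subsets
  alloc_class <- function(n_c) {
    quota <- n_c * c(train = n_train, validation = n_val, test = n_test) / N
    base <- floor(quota)
    rem <- quota - base
    short <- n_c - sum(base)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      base[add] <- base[add] + 1
    }
    base
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  parts <- lapply(seq_len(n_reps), function(rep_i) {
    tr <- va <- te <- integer(0)
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      a <- alloc_class(length(idx))
      tr <- c(tr, idx[seq_len(a["train"])])
      va <- c(va, idx[a["train"] + seq_len(a["validation"])])
      te <- c(te, idx[a["train"] + a["validation"] + seq_len(a["test"])])
    }
    list(train = sort(tr), validation = sort(va), test = sort(te))
  })
  structure(parts, class = c("ehg_partitions", "list"), seed = seed)
}

#' Fit a PCA map retaining a fixed share of variance
#'
#' Features are standardized by their training means and SDs (zero-variance
#' features dropped with a message), then projected on the smallest number of
#' principal components whose cumulative explained variance reaches
#' `var_retained`.
#'
#' @param x numeric matrix or data frame of training features.
#' @param var_retained cumulative explained-variance threshold (default 0.98).
#' @return An `ehg_pca` list: `center`, `scale`, `loadings`, `n_components`,
#'   `variance_retained`, `kept` (feature names used).
#' @export
fit_pca <- function(x, var_retained = 0.98) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sdv <- apply(x, 2, stats::sd)
  drop <- sdv == 0 | is.na(sdv)
  if (any(drop))
    message("dropping zero-variance feature(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  keep <- colnames(x)[!drop]
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  ncomp <- which(cum >= var_retained)[1]
  out <- list(center = pc$center, scale = pc$scale,
              loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
              n_components = ncomp, variance_retained = cum[ncomp], kept = keep)
  class(out) <- "ehg_pca"
  out
}

#' Project features through a fitted PCA map
#'
#' @param map an `ehg_pca` from [fit_pca()].
#' @param x matrix or data frame with the original feature columns.
#' @return Score matrix with `map$n_components` columns.
#' @export
apply_pca <- function(map, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x <- x[, map$kept, drop = FALSE]
  z <- sweep(sweep(x, 2, map$center), 2, map$scale, "/")
  z %*% map$loadings
}
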