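subset_table <- function(table, idx) {
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_names") <- attr(table, "feature_names")
  attr(out, "input_set") <- attr(table, "input_set")
  class(out) <- class(table)
  out
}

#' Prepare the balanced, partitioned, PCA-reduced classifier inputs
#'
#' Default mode replicates the study pipeline order: SMOTE on the full table,
#' then the repeated stratified holdout partitions over the balanced table,
#' then a PCA map fitted on each partition's training subset and applied to
#' all three subsets. This order lets synthetic minority samples share parents
#' across subsets (a known information-leakage concern); `leak_safe = TRUE`
#' instead partitions the original table and applies SMOTE and the PCA fit
#' inside each training fold only, leaving validation and test subsets at the
#' original class balance.
#'
#' @param table an `ehg_table` from [build_table()].
#' @param n_reps number of holdout repetitions (default 30).
#' @param seed integer seed governing SMOTE and partitioning.
#' @param leak_safe logical; see above.
#' @param smote_ratio,smote_k see [smote()].
#' @param var_retained PCA explained-variance threshold (default 0.98).
#' @return An `ehg_design`: `partitions`, `folds` (per partition: `xtr`,
#'   `ytr`, `xval`, `yval`, `xte`, `yte`, `pca`), `leak_safe`, `table_n`.
#' @export
prepare_design <- function(table, n_reps = 30, seed = 1L, leak_safe = FALSE,
                           smote_ratio = 3, smote_k = 5, var_retained = 0.98) {
  fn <- attr(table, "feature_names")
  if (!leak_safe) {
    balanced <- smote(table, ratio = smote_ratio, k = smote_k, seed = seed)
    partitions <- make_partitions(balanced, n_reps = n_reps, seed = seed + 1L)
    folds <- lapply(partitions, function(p) {
      pca <- fit_pca(balanced[p$train, fn], var_retained = var_retained)
      list(xtr = apply_pca(pca, balanced[p$train, fn]),
           ytr = balanced$label[p$train],
           xval = apply_pca(pca, balanced[p$validation, fn]),
           yval = balanced$label[p$validation],
           xte = apply_pca(pca, balanced[p$test, fn]),
           yte = balanced$label[p$test],
           pca = pca)
    })
    n_used <- nrow(balanced)
  } else {
    partitions <- make_partitions(table, n_reps = n_reps, seed = seed + 1L)
    folds <- lapply(seq_along(partitions), function(pi) {
      p <- partitions[[pi]]
      aug <- smote(subset_table(table, p$train), ratio = smote_ratio,
                   k = smote_k, seed = seed + 100L + pi)
      pca <- fit_pca(aug[, fn], var_retained = var_retained)
      list(xtr = apply_pca(pca, aug[, fn]),
           ytr = aug$label,
           xval = apply_pca(pca, table[p$validation, fn]),
           yval = table$label[p$validation],
           xte = apply_pca(pca, table[p$test, fn]),
           yte = table$label[p$test],
           pca = pca)
    })
    n_used <- nrow(table)
  }
  structure(list(partitions = partitions, folds = folds, leak_safe = leak_safe,
                 table_n = n_used),
            class = "ehg_design")
}

#' Run the classifier design and assessment for one input table
#'
#' Convenience wrapper: prepares the design, grid-searches each requested
#' classifier once (seed ledger included), selects hyperparameters under each
#' optimization criterion, and evaluates the selected models on the
#' validation and test subsets of every partition.
#'
#' @param table an `ehg_table`.
#' @param kinds classifier kinds to run (subset of `c("rf", "elm", "knn")`).
#' @param criteria optimization criteria (subset of `c("f1", "sensitivity")`).
#' @param grids named list of hyperparameter grids per kind; defaults to
#'   [default_grid()] for each.
#' @param n_reps,seed,leak_safe,smote_ratio,smote_k,var_retained see
#'   [prepare_design()].
#' @param n_seeds candidate seeds per combination and partition.
#' @return List with `design`, `searches`, `selections` (named
#'   `<kind>_<criterion>`), and `metrics`, a long data frame with one row per
#'   (kind, criterion, subset, partition).
#' @export
run_experiment <- function(table, kinds = c("rf", "elm", "knn"),
                           criteria = c("f1", "sensitivity"), grids = list(),
                           n_reps = 30, n_seeds = 30, seed = 1L,
                           leak_safe = FALSE, smote_ratio = 3, smote_k = 5,
                           var_retained = 0.98) {
  design <- prepare_design(table, n_reps = n_reps, seed = seed,
                           leak_safe = leak_safe, smote_ratio = smote_ratio,
                           smote_k = smote_k, var_retained = var_retained)
  input_set <- attr(table, "input_set")
  if (is.null(input_set)) input_set <- NA_integer_
  searches <- list()
  selections <- list()
  metric_rows <- list()
  for (kind in kinds) {
    grid <- if (!is.null(grids[[kind]])) grids[[kind]] else default_grid(kind)
    searches[[kind]] <- grid_search(design, kind, grid, n_seeds = n_seeds,
                                    seed_base = seed * 1000L)
    for (crit in criteria) {
      sel <- select_model(searches[[kind]], crit)
      key <- paste(kind, crit, sep = "_")
      selections[[key]] <- sel
      for (sub in c("validation", "test")) {
        ev <- evaluate_selected(design, sel, subset = sub)
        metric_rows[[length(metric_rows) + 1]] <- cbind(
          data.frame(classifier = kind, criterion = crit,
                     input_set = input_set, subset = sub,
                     partition = seq_len(nrow(ev$metrics))),
          ev$metrics)
      }
    }
  }
  list(design = design, searches = searches, selections = selections,
       metrics = do.call(rbind, metric_rows))
}
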