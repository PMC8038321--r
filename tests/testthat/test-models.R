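blobs <- function(n = 100, sep = 6, seed = 51) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, 0, 1), n / 2, 2),
             matrix(rnorm(n, sep, 1), n / 2, 2))
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

xor_data <- function(reps = 25, noise = 0.05, seed = 52) {
  set.seed(seed)
  base <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  x <- base[rep(1:4, reps), ] + matrix(rnorm(8 * reps, 0, noise), 4 * reps, 2)
  list(x = x, y = rep(c(0L, 0L, 1L, 1L), reps))
}

test_that("random forest separates blobs, fails XOR at depth 1, is seed-deterministic", {
  b <- blobs()
  m <- train_rf(b$x, b$y, n_trees = 100, seed = 3)
  expect_equal(mean(predict_class(m, b$x) == b$y), 1)

  xo <- xor_data()
  m1 <- train_rf(xo$x, xo$y, n_trees = 100, max_depth = 1, seed = 3)
  expect_lte(mean(predict_class(m1, xo$x) == xo$y), 0.75)

  s1 <- predict_score(train_rf(b$x, b$y, n_trees = 50, seed = 9), b$x)
  s2 <- predict_score(train_rf(b$x, b$y, n_trees = 50, seed = 9), b$x)
  expect_identical(s1, s2)
  expect_error(train_rf(b$x, rep(1, nrow(b$x))), "single class")
})

test_that("identity-activation ELM reduces to linear least squares", {
  b <- blobs()
  m <- train_elm(b$x, b$y, n_hidden = 10, activation = "identity", seed = 5)
  raw <- 2 * predict_score(m, b$x) - 1
  fit <- lm.fit(cbind(1, b$x), ifelse(b$y == 1, 1, -1))
  expect_equal(raw, unname(cbind(1, b$x) %*% fit$coefficients)[, 1], tolerance = 1e-6)
  expect_equal(mean(predict_class(m, b$x) == b$y), 1)
})

test_that("ELM solves XOR for nearly all seeds and is seed-deterministic", {
  xo <- xor_data(reps = 1, noise = 0)
  acc <- vapply(1:100, function(s) {
    m <- train_elm(xo$x, xo$y, n_hidden = 10, activation = "tanh", seed = s)
    mean(predict_class(m, xo$x) == xo$y)
  }, numeric(1))
  expect_gte(mean(acc == 1), 0.95)

  b <- blobs()
  m1 <- train_elm(b$x, b$y, 25, "sigmoid", seed = 7)
  m2 <- train_elm(b$x, b$y, 25, "sigmoid", seed = 7)
  expect_identical(m1$beta, m2$beta)
  expect_error(train_elm(b$x, b$y, 0), "n_hidden")
})

test_that("KNN scoring follows the kernel-weighted neighbor rule", {
  b <- blobs(n = 40)
  m <- train_knn(b$x, b$y, k = 1)
  expect_equal(predict_score(m, b$x[3, , drop = FALSE]), 0)  # its own label (class 0)
  expect_equal(predict_score(m, b$x[25, , drop = FALSE]), 1)

  # rectangular kernel equals the unweighted neighbor fraction
  set.seed(53)
  q <- matrix(rnorm(20), 10, 2)
  m5 <- train_knn(b$x, b$y, k = 5, kernel = "rectangular")
  sc <- predict_score(m5, q)
  oracle <- apply(q, 1, function(qq) {
    d <- sqrt(colSums((t(b$x) - qq)^2))
    mean(b$y[order(d)[1:5]] == 1)
  })
  expect_equal(unname(sc), unname(oracle))

  # Minkowski order changes the nearest neighbor on an asymmetric layout
  xtr <- rbind(c(1.2, 0), c(0.75, 0.75), c(10, 10))
  ytr <- c(0L, 1L, 0L)
  q0 <- matrix(c(0, 0), 1)
  m_l1 <- train_knn(xtr, ytr, k = 1, minkowski_p = 1)
  m_l2 <- train_knn(xtr, ytr, k = 1, minkowski_p = 2)
  expect_equal(predict_class(m_l1, q0), 0L)  # L1: (1.2,0) closer
  expect_equal(predict_class(m_l2, q0), 1L)  # L2: (0.75,0.75) closer

  expect_error(train_knn(b$x, b$y, k = 100), "exceeds")
})

small_design <- function(seed = 61, n_reps = 6) {
  set.seed(seed)
  n <- 60
  x <- rbind(matrix(rnorm(n, 0, 1.2), n / 2, 2),
             matrix(rnorm(n, 2.2, 1.2), n / 2, 2))
  tab <- cbind(data.frame(id = sprintf("r%02d", 1:n), label = rep(c(0L, 1L), each = n / 2),
                          origin = "real"), as.data.frame(x))
  attr(tab, "feature_names") <- c("V1", "V2")
  attr(tab, "input_set") <- 4L
  class(tab) <- c("ehg_table", "data.frame")
  prepare_design(tab, n_reps = n_reps, seed = seed)
}

test_that("grid search stores validation-chosen seeds before any test use", {
  des <- small_design()
  grid <- list(n_hidden = c(5, 20), activation = "tanh")
  sr <- grid_search(des, "elm", grid, n_seeds = 4, seed_base = 100)
  expect_equal(dim(sr$seeds), c(2, 6))
  expect_true(all(sr$seeds >= 100 & sr$seeds <= 103))
  # KNN has no training randomness: repeated searches are identical
  sk1 <- grid_search(des, "knn", list(k = c(3, 5), minkowski_p = 2,
                                      kernel = "rectangular"))
  sk2 <- grid_search(des, "knn", list(k = c(3, 5), minkowski_p = 2,
                                      kernel = "rectangular"))
  expect_identical(sk1$val_metrics, sk2$val_metrics)
  expect_true(all(is.na(sk1$seeds)))
})

test_that("model selection follows each optimization criterion", {
  des <- small_design()
  grid <- list(n_hidden = 20, activation = "tanh")
  sr <- grid_search(des, "elm", grid, n_seeds = 3)
  expect_equal(select_model(sr, "f1")$combo_index, 1)
  expect_equal(select_model(sr, "sensitivity")$combo_index, 1)

  # constructed search: X has higher mean sensitivity, Y higher mean F1
  fake <- structure(list(
    kind = "knn",
    combos = data.frame(k = c(3, 5)),
    mean_f1 = c(70, 80),
    mean_sens = c(95, 85),
    seeds = matrix(NA_integer_, 2, 6),
    val_metrics = list(data.frame(f1 = 70, sensitivity = 95, specificity = 50),
                       data.frame(f1 = 80, sensitivity = 85, specificity = 70))),
    class = "ehg_search")
  expect_equal(select_model(fake, "f1")$combo_index, 2)
  expect_equal(select_model(fake, "sensitivity")$combo_index, 1)

  # dominance: A at least as good on both -> chosen under both criteria
  fake$mean_f1 <- c(85, 80); fake$mean_sens <- c(90, 85)
  expect_equal(select_model(fake, "f1")$combo_index, 1)
  expect_equal(select_model(fake, "sensitivity")$combo_index, 1)
})

test_that("selected models evaluate with stored seeds on all subsets", {
  des <- small_design()
  sr <- grid_search(des, "elm", list(n_hidden = c(10, 30), activation = "sigmoid"),
                    n_seeds = 3)
  sel <- select_model(sr, "f1")
  ev_val <- evaluate_selected(des, sel, "validation")
  ev_test <- evaluate_selected(des, sel, "test")
  expect_equal(nrow(ev_val$metrics), 6)
  # validation metrics at stored seeds reproduce the search's bookkeeping
  expect_equal(ev_val$metrics$f1, sel$val_metrics$f1)
  expect_true(all(ev_test$metrics$f1 >= 0 & ev_test$metrics$f1 <= 100, na.rm = TRUE))
  expect_length(ev_test$scores, 6)
})
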