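test_that("the hinge objective matches literal summation", {
  set.seed(11)
  x <- matrix(as.numeric(runif(20 * 6) < 0.4), 20, 6)
  y <- sample(c(-1, 1), 20, replace = TRUE)
  des <- design_from_dense(x, y)

  # w = 0: each example contributes exactly C
  expect_equal(hinge_objective(numeric(6), design_subset(des, 1:5), "L2", C = 1), 5)
  # all margins >= 1: only the regularizer remains
  xp <- diag(6); yp <- rep(1, 6)
  dp <- design_from_dense(xp, yp)
  w_big <- rep(2, 6)
  expect_equal(hinge_objective(w_big, dp, "L1", C = 3), sum(abs(w_big)))

  for (reg in c("L1", "L2")) {
    w <- rnorm(6)
    expect_equal(hinge_objective(w, des, reg, C = 2.5),
                 oracle_objective(w, x, y, 2.5, reg), tolerance = 1e-12)
  }
  expect_error(hinge_objective(numeric(5), des), class = "cpisketch_validation_error")
})

test_that("the solver separates a trivial axis problem and vanishes as C -> 0", {
  x <- rbind(c(1, 0), c(0, 1))
  y <- c(1, -1)
  des <- design_from_dense(x, y)
  fit <- train_linear_svm(des, "L2", C = 100)
  margins <- y * decision_scores(fit, des)
  expect_true(all(margins >= 1 - 1e-6))
  expect_gt(fit$weights[1], 0)

  tiny <- train_linear_svm(des, "L2", C = 1e-9)
  expect_true(all(abs(tiny$weights) < 1e-6))
  tiny1 <- train_linear_svm(des, "L1", C = 1e-9)
  expect_true(all(abs(tiny1$weights) < 1e-6))
})

test_that("coordinate descent reaches the subgradient oracle's objective on a planted halfspace", {
  hs <- make_halfspace(400, 50, seed = 21)
  des <- design_from_dense(hs$x, hs$y)
  for (reg in c("L2", "L1")) {
    fit <- suppressWarnings(train_linear_svm(des, reg, C = 1, tolerance = 1e-6,
                                             max_iterations = 5000))
    acc <- mean(sign(decision_scores(fit, des)) == hs$y)
    expect_gte(acc, 0.99)
    best <- oracle_subgradient(hs$x, hs$y, C = 1, reg = reg, iters = 20000)
    # the CD solution must be at least as good as the oracle up to 1%
    expect_lt(fit$objective, best * 1.01)
    expect_equal(fit$objective,
                 hinge_objective(fit$weights, des, reg, C = 1),
                 tolerance = 1e-10)
  }
})

test_that("the L2 solution agrees with an independent dual QP solver", {
  skip_if_not_installed("kernlab")
  hs <- make_halfspace(30, 8, seed = 5)
  des <- design_from_dense(hs$x, hs$y)
  C <- 2
  fit <- suppressWarnings(train_linear_svm(des, "L2", C = C, tolerance = 1e-9,
                                           max_iterations = 5000))
  # box-constrained dual: max sum(alpha) - 0.5 alpha' Q alpha, 0 <= alpha <= C
  # (small ridge keeps the interior-point KKT system well conditioned)
  Q <- (hs$y %o% hs$y) * tcrossprod(hs$x)
  qp <- kernlab::ipop(c = rep(-1, 30), H = Q + diag(1e-3, 30),
                      A = matrix(1, 1, 30), b = 0, r = 60,
                      l = rep(0, 30), u = rep(C, 30), sigf = 7, maxiter = 100)
  alpha <- kernlab::primal(qp)
  w_dual <- as.numeric(crossprod(hs$x, alpha * hs$y))
  dual_obj <- oracle_objective_fast(w_dual, hs$x, hs$y, C, "L2")
  expect_lte(fit$objective, dual_obj * (1 + 1e-3))
  expect_lt(abs(fit$objective - dual_obj) / dual_obj, 0.01)
})

test_that("the objective trace is monotone and refits are bitwise identical", {
  hs <- make_halfspace(150, 30, seed = 33)
  des <- design_from_dense(hs$x, hs$y)
  for (reg in c("L1", "L2")) {
    f1 <- train_linear_svm(des, reg, C = 0.5, seed = 4)
    f2 <- train_linear_svm(des, reg, C = 0.5, seed = 4)
    expect_true(all(diff(f1$trace) <= 1e-12))
    expect_identical(f1$weights, f2$weights)
    expect_lt(abs(f1$objective - f2$objective), 1e-10)
  }
})

test_that("L1 fits are at least as sparse as L2 fits", {
  for (seed in 1:3) {
    hs <- make_halfspace(200, 60, seed = seed)
    des <- design_from_dense(hs$x, hs$y)
    l1 <- train_linear_svm(des, "L1", C = 1)
    l2 <- train_linear_svm(des, "L2", C = 1)
    expect_lte(sum(l1$weights != 0), sum(abs(l2$weights) > 1e-6))
  }
})

test_that("decision scores are plain dot products in both modes", {
  # indicator weight vector
  x <- rbind(c(1, 0, 1), c(0, 1, 0))
  des <- design_from_dense(x, c(1, -1))
  w <- c(0, 1, 0)
  expect_equal(as.numeric(des$x %*% w), c(0, 1))

  sim <- generate_synthetic_dataset(strong_config(2))
  feats <- pair_features(sim$dataset)
  feats <- feats[lengths(feats$features) > 0, ]
  fam <- hash_family(7, 80, 16, master_seed = 6)
  enc <- compact_encode(feats, fam)
  des_c <- design_compact(enc, fam)
  fit <- train_linear_svm(des_c, "L2", C = 0.1)
  sc <- decision_scores(fit, enc[1:10, ])
  naive <- vapply(1:10, function(i) {
    sum(fit$weights[which(compact_dense(enc$bins[[i]], fam) == 1)])
  }, numeric(1))
  expect_equal(sc, naive, tolerance = 1e-12)
  expect_equal(predict(fit, enc[1:10, ], type = "class"),
               ifelse(sc >= 0, 1L, -1L))
})

test_that("models serialize to JSON and back without changing predictions", {
  sim <- generate_synthetic_dataset(strong_config(3))
  feats <- pair_features(sim$dataset)
  feats <- feats[lengths(feats$features) > 0, ]
  fam <- hash_family(9, 80, 16, master_seed = 2)
  enc <- compact_encode(feats, fam)
  fit <- train_linear_svm(design_compact(enc, fam), "L1", C = 1)

  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(decision_scores(back, enc), decision_scores(fit, enc))
  expect_equal(back$regularization, "L1")

  g <- glance(fit)
  expect_equal(g$n_nonzero, sum(fit$weights != 0))
  td <- tidy(fit)
  expect_equal(nrow(td), g$n_nonzero)
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(1, 4, 2)
  expect_error(train_linear_svm(design_from_dense(x, rep(1, 4)), "L2"),
               class = "cpisketch_degenerate_error")
  des <- design_from_dense(x, c(1, 1, -1, -1))
  expect_error(train_linear_svm(des, "L2", C = -1),
               class = "cpisketch_validation_error")
})
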