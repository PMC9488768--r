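test_that("initialization is seeded, bounded, and centred", {
  m1 <- ann_init(7); m2 <- ann_init(7)
  expect_identical(m1, m2)
  expect_false(identical(ann_init(8)$w1, m1$w1))

  draws <- c(ann_init(1, n_in = 2000, n_hidden = 50, n_out = 7)$w1)
  expect_gte(min(draws), -0.5)
  expect_lte(max(draws), 0.5)
  se <- (1 / sqrt(12)) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("the forward pass is a proper softmax classifier", {
  m <- ann_init(1)
  m$w1[] <- 0; m$b1[] <- 0; m$w2[] <- 0; m$b2[] <- 0
  p <- ann_forward(m, rep(0.3, 512))
  expect_equal(p, rep(1 / 7, 7))

  m <- ann_init(2)
  x <- runif(512)
  p1 <- ann_forward(m, x)
  m_shift <- m; m_shift$b2 <- m$b2 + 3.7  # constant logit shift
  expect_equal(ann_forward(m_shift, x), p1, tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(ann_forward(m, runif(100)), "does not match")
})

test_that("the forward pass matches a scalar loop oracle to 1e-12", {
  set.seed(10)
  m <- ann_init(3, n_in = 6, n_hidden = 4, n_out = 3)
  x <- runif(6)
  h <- numeric(4)
  for (i in 1:4) h[i] <- 1 / (1 + exp(-(sum(m$w1[i, ] * x) + m$b1[i])))
  z <- numeric(3)
  for (i in 1:3) z[i] <- sum(m$w2[i, ] * h) + m$b2[i]
  p_oracle <- exp(z) / sum(exp(z))
  expect_equal(ann_forward(m, x), p_oracle, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  m <- ann_init(4)
  x <- matrix(runif(10 * 512), 10, 512)
  y <- sample(1:7, 10, replace = TRUE); y[1:7] <- 1:7
  g <- lesiontex:::ann_loss_grad(m, x, y)
  for (field in c("w1", "b1", "w2", "b2")) {
    idx <- sample(length(m[[field]]), min(40, length(m[[field]])))
    num <- numeric_grad(m, x, y, field, idx)
    ana <- g[[paste0("d", field)]][idx]
    rel <- abs(ana - num) / pmax(abs(ana) + abs(num), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training separates two linearly separable clusters", {
  set.seed(12)
  n <- 20
  x <- rbind(matrix(runif(n * 512, 0, 0.2), n, 512),
             matrix(runif(n * 512, 0.8, 1.0), n, 512))
  y <- rep(1:2, each = n)
  fit <- ann_train(ann_init(13), x, y,
                   ann_config(max_epochs = 2000, patience = 2000, seed = 14))
  expect_equal(mean(ann_predict(fit, x) == y), 1)
})

test_that("early stopping respects patience and restores the best weights", {
  set.seed(15)
  x <- matrix(runif(40 * 512), 40, 512)
  y <- rep(1:2, 20)
  fit0 <- ann_train(ann_init(16), x, y,
                    ann_config(patience = 0, max_epochs = 500, seed = 17))
  # patience 0: stops at the first epoch whose validation loss fails to improve
  first_bad <- which(diff(c(Inf, fit0$history$val_loss)) >= 0)[1]
  expect_equal(fit0$stopped_epoch, first_bad)
  expect_equal(fit0$best_val_loss, min(fit0$history$val_loss))

  fit1 <- ann_train(ann_init(16), x, y,
                    ann_config(patience = 20, max_epochs = 200, seed = 17))
  expect_equal(fit1$best_val_loss, min(fit1$history$val_loss))
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_named(tidy(fit1), c("epoch", "train_loss", "val_loss"))
  expect_equal(glance(fit1)$best_val_loss, min(fit1$history$val_loss))
})

test_that("training is deterministic and rejects degenerate labels", {
  set.seed(18)
  x <- matrix(runif(30 * 512), 30, 512)
  y <- rep(1:3, 10)
  cfg <- ann_config(max_epochs = 50, seed = 19)
  f1 <- ann_train(ann_init(20), x, y, cfg)
  f2 <- ann_train(ann_init(20), x, y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model, f2$model)

  expect_error(ann_train(ann_init(21), x, rep(1L, 30), cfg),
               class = "degenerate_labels")
})

test_that("prediction is the argmax with low-index tie-breaking", {
  m <- ann_init(1)
  m$w1[] <- 0; m$b1[] <- 0; m$w2[] <- 0; m$b2[] <- 0
  expect_equal(ann_predict(m, rep(0.5, 512)), 1L)  # 7-way tie -> class 1

  set.seed(22)
  for (i in 1:100) {
    mm <- ann_init(i, n_in = 10, n_hidden = 5, n_out = 4)
    x <- runif(10)
    p <- ann_forward(mm, x)
    scan_best <- 1
    for (k in 2:4) if (p[k] > p[scan_best]) scan_best <- k
    expect_equal(ann_predict(mm, x), scan_best)
  }
})

test_that("models survive a JSON round trip", {
  m <- ann_init(23, n_in = 8, n_hidden = 3, n_out = 4)
  f <- withr::local_tempfile(fileext = ".json")
  save_ann(m, f)
  m2 <- load_ann(f)
  x <- runif(8)
  expect_equal(ann_forward(m2, x), ann_forward(m, x), tolerance = 1e-12)
})
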