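test_that("the default network stays at desk scale", {
  m <- cnn_build(cnn_config())
  expect_lt(m$n_params, 500000)
  # analytic count agrees with the actual weight tensors
  actual <- length(m$weights$dense_w) + length(m$weights$dense_b) +
    length(m$weights$out_w) + length(m$weights$out_b) +
    sum(vapply(m$weights$conv_w, length, numeric(1))) +
    sum(vapply(m$weights$conv_b, length, numeric(1)))
  expect_equal(m$n_params, actual)
  expect_error(cnn_build(cnn_config(input_size = c(4, 4))), "fit|collapse")
})

test_that("analytic gradients match finite differences", {
  cfg <- cnn_config(input_size = c(14, 14), conv_filters = c(3L, 4L),
                    kernel = 3, pool = 2, dense_units = 5, dropout = 0,
                    seed = 5)
  m <- cnn_build(cfg)
  withr::with_seed(1, {
    x <- array(runif(14 * 14 * 3), c(14, 14, 3))
  })
  y <- c(0, 1, 1)
  loss_at <- function(w) mammocheat:::cnn_grad_cpp(
    w, x, y, cfg$conv_filters, cfg$kernel, cfg$pool, cfg$dense_units,
    0.7, 1.3)$loss
  g <- mammocheat:::cnn_grad_cpp(m$weights, x, y, cfg$conv_filters,
                                 cfg$kernel, cfg$pool, cfg$dense_units,
                                 0.7, 1.3)$grads
  eps <- 1e-6
  numeric_grad <- function(mutate) {
    wp <- mutate(m$weights, eps); wm <- mutate(m$weights, -eps)
    (loss_at(wp) - loss_at(wm)) / (2 * eps)
  }
  checks <- list(
    list(a = g$conv_w[[1]][5],
         f = function(w, e) { w$conv_w[[1]][5] <- w$conv_w[[1]][5] + e; w }),
    list(a = g$conv_w[[2]][11],
         f = function(w, e) { w$conv_w[[2]][11] <- w$conv_w[[2]][11] + e; w }),
    list(a = g$conv_b[[1]][2],
         f = function(w, e) { w$conv_b[[1]][2] <- w$conv_b[[1]][2] + e; w }),
    list(a = g$dense_w[17],
         f = function(w, e) { w$dense_w[17] <- w$dense_w[17] + e; w }),
    list(a = g$out_w[3],
         f = function(w, e) { w$out_w[3] <- w$out_w[3] + e; w }),
    list(a = g$out_b[1],
         f = function(w, e) { w$out_b[1] <- w$out_b[1] + e; w })
  )
  for (ch in checks)
    expect_equal(ch$a, numeric_grad(ch$f), tolerance = 1e-5)
})

test_that("weight initialization and training are seed-deterministic", {
  cfg <- tiny_cnn_config(seed = 9)
  expect_identical(cnn_build(cfg)$weights, cnn_build(cfg)$weights)
  withr::with_seed(2, {
    imgs <- lapply(1:12, function(i)
      quantize8(matrix(runif(2500, 0, 255), 50, 50)))
  })
  y <- rep_len(c(0, 1), 12)
  t1 <- cnn_train(cnn_build(cfg), imgs, y, seed = 4, epochs = 2)
  t2 <- cnn_train(cnn_build(cfg), imgs, y, seed = 4, epochs = 2)
  expect_identical(t1$weights, t2$weights)
  expect_equal(nrow(t1$history), 2)   # history length = epochs run
  s1 <- predict_proba(t1, imgs)
  expect_identical(s1, predict_proba(t2, imgs))
})

test_that("scores are probabilities and permutation-equivariant", {
  cfg <- tiny_cnn_config()
  m <- cnn_build(cfg)
  withr::with_seed(3, {
    imgs <- lapply(1:8, function(i)
      quantize8(matrix(runif(2500, 0, 255), 50, 50)))
    perm <- sample(8)
  })
  p <- predict_proba(m, imgs)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict_proba(m, imgs[perm]), p[perm])
  expect_equal(predict(m, imgs, type = "class"), as.integer(p >= 0.5))
  expect_error(predict_proba(m, list(matrix(0L, 10, 10))), "expected")
})

test_that("the validation split follows the rounding rule and is disjoint", {
  cfg <- tiny_cnn_config()
  withr::with_seed(5, {
    imgs <- lapply(1:666, function(i) quantize8(matrix(runif(2500, 0, 255),
                                                       50, 50)))
  })
  y <- rep_len(c(0, 1), 666)
  tr <- cnn_train(cnn_build(cfg), imgs, y, val_fraction = 0.25, seed = 1,
                  epochs = 1)
  expect_equal(length(tr$val_idx), 166)   # round(166.5), halves to even
  expect_length(intersect(tr$val_idx, setdiff(seq_len(666), tr$val_idx)), 0)
})

test_that("training fails cleanly on single-class data", {
  cfg <- tiny_cnn_config()
  imgs <- lapply(1:8, function(i) matrix(100L, 50, 50))
  expect_error(cnn_train(cnn_build(cfg), imgs, rep(1, 8), seed = 1),
               "single class")
})

test_that("a separable bright-versus-dark task is learned to perfection", {
  task <- separable_task(n = 40)
  cfg <- cnn_config(batch_size = 4, seed = 7)
  tr <- cnn_train(cnn_build(cfg), task$images, task$labels,
                  val_fraction = 0.25, seed = 7, epochs = 20)
  expect_equal(tr$history$acc[20], 1)
  scores <- predict_proba(tr, task$images)
  expect_true(all((scores >= 0.5) == (task$labels == 1)))
})
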