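test_that("activation functions match their definitions", {
  expect_equal(bltrecon:::relu(c(-3, 0, 2)), c(0, 0, 2))
  expect_equal(bltrecon:::sigmoid(0), 0.5)
  expect_equal(bltrecon:::sigmoid(1e3), 1)
})

test_that("the network maps flux vectors to (0,1) source scores", {
  m <- build_1dcnn(100, 50, seed = 2)
  phi <- runif(100)
  p <- predict(m, phi)
  expect_length(p, 50)
  expect_true(all(p > 0 & p < 1))
  # deterministic given weights
  expect_identical(p, predict(m, phi))
  # batch input
  P <- predict(m, matrix(runif(300), 3))
  expect_equal(dim(P), c(3, 50))
  expect_error(predict(m, runif(99)), "does not match")
  # a zeroed output layer gives exactly 0.5 everywhere
  m0 <- m
  nl <- length(m0$layers)
  m0$layers[[nl]]$W[] <- 0
  m0$layers[[nl]]$b[] <- 0
  expect_true(all(predict(m0, phi) == 0.5))
})

test_that("architecture validation rejects impossible conv stacks", {
  expect_error(model_spec(list(list(out_ch = 4, kernel = 3, stride = 1))),
               "3 conv layers")
  bad <- model_spec(list(list(out_ch = 4, kernel = 9, stride = 9),
                         list(out_ch = 4, kernel = 9, stride = 9),
                         list(out_ch = 4, kernel = 9, stride = 9)))
  expect_error(build_1dcnn(20, 10, bad), "below length 1")
})

test_that("parameter counting is exact", {
  # conv layer (in 1, out 4, kernel 3) contributes 1*4*3 + 4 = 16
  spec <- model_spec(list(list(out_ch = 4, kernel = 3, stride = 2),
                          list(out_ch = 2, kernel = 2, stride = 2),
                          list(out_ch = 2, kernel = 2, stride = 2)))
  m <- build_1dcnn(20, 5, spec)
  l1 <- m$layers[[1]]
  expect_equal(length(l1$W) + length(l1$b), 16)
  manual <- sum(vapply(m$layers, function(l) length(l$W) + length(l$b),
                       numeric(1)))
  expect_equal(count_parameters(m), manual)
  # a bare fully connected map 17 -> 5831 with bias
  fc <- build_mlp_baseline(17, 5831, hidden = integer(0))
  expect_equal(count_parameters(fc), 17 * 5831 + 5831)
})

test_that("default architecture meets the parameter budget at full scale", {
  # full-scale output dimension with this package's surface dimension
  m <- build_1dcnn(1250, 5831)
  n_cnn <- count_parameters(m)
  expect_gte(n_cnn, 0.5e5)
  expect_lte(n_cnn, 2e5)
  mlp <- build_mlp_baseline(1250, 5831)
  expect_gt(count_parameters(mlp), n_cnn)
  # at least 80% fewer parameters than the fully connected baseline
  expect_lte(n_cnn, 0.2 * count_parameters(mlp))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  N <- 40; M <- 15; B <- 3
  spec <- model_spec(list(list(out_ch = 3, kernel = 5, stride = 3),
                          list(out_ch = 4, kernel = 3, stride = 2),
                          list(out_ch = 5, kernel = 4, stride = 4)))
  models <- list(cnn = build_1dcnn(N, M, spec, seed = 7),
                 mlp = build_mlp_baseline(N, M, hidden = c(10, 8),
                                          seed = 3))
  phi <- matrix(runif(B * N), B, N)
  X <- matrix(rbinom(B * M, 1, 0.3), B, M)
  for (m in models) {
    for (loss_fn in list(bltrecon:::bce_loss, bltrecon:::l2_loss)) {
      fw <- bltrecon:::nn_forward(m, phi, keep_cache = TRUE)
      gr <- bltrecon:::nn_backward(m, fw$caches,
                                   loss_fn(fw$logits, X)$grad)
      eps <- 1e-6
      for (li in seq_along(m$layers)) {
        P <- m$layers[[li]]$W
        for (id in sample(length(P), 4)) {
          m2 <- m
          m2$layers[[li]]$W[id] <- P[id] + eps
          l1 <- loss_fn(bltrecon:::nn_forward(m2, phi)$logits, X)$loss
          m2$layers[[li]]$W[id] <- P[id] - eps
          l0 <- loss_fn(bltrecon:::nn_forward(m2, phi)$logits, X)$loss
          fd <- (l1 - l0) / (2 * eps)
          expect_equal(gr[[li]]$dW[id], fd, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("uninformative predictions cost ln 2 per node under BCE", {
  X <- matrix(rbinom(60, 1, 0.4), 4)
  logits <- matrix(0, 4, 15)   # sigmoid(0) = 0.5 everywhere
  expect_equal(bltrecon:::bce_loss(logits, X)$loss, log(2))
})

test_that("training reduces the loss, selects the best epoch, and is
           reproducible", {
  set.seed(5)
  n <- 24; N <- 30; M <- 40
  phi <- matrix(runif(n * N), n)
  X <- Matrix::Matrix(matrix(rbinom(n * M, 1, 0.2), n), sparse = TRUE)
  ds <- structure(list(
    phi = phi, phi_raw = phi, X = X,
    meta = data.frame(id = 1:n),
    splits = list(train = 1:16, val = 17:20, test = 21:24),
    samples = list(), config = dataset_config(seed = 1),
    provenance = list(config_hash = "x")), class = "blt_dataset")
  spec <- model_spec(list(list(out_ch = 4, kernel = 5, stride = 2),
                          list(out_ch = 4, kernel = 3, stride = 2),
                          list(out_ch = 4, kernel = 3, stride = 2)))
  cfg <- train_config(epochs = 40, batch_size = 8, seed = 9)
  tr1 <- train_model(build_1dcnn(N, M, spec, seed = 3), ds, cfg)
  expect_lt(tail(tr1$history$train_loss, 1), tr1$history$train_loss[1])
  # selected epoch attains the minimum recorded validation loss
  expect_equal(tr1$selected_epoch, which.min(tr1$history$val_loss))
  expect_equal(min(tr1$history$val_loss),
               tr1$history$val_loss[tr1$selected_epoch])
  # bitwise reproducibility of history and weights
  tr2 <- train_model(build_1dcnn(N, M, spec, seed = 3), ds, cfg)
  expect_identical(tr1$history, tr2$history)
  expect_identical(tr1$model$layers, tr2$model$layers)
  # a different shuffling seed changes the trajectory
  tr3 <- train_model(build_1dcnn(N, M, spec, seed = 3), ds,
                     train_config(epochs = 40, batch_size = 8, seed = 10))
  expect_false(identical(tr1$history, tr3$history))
  # the L2 objective trains too
  tr4 <- train_model(build_1dcnn(N, M, spec, seed = 3), ds,
                     train_config(epochs = 10, batch_size = 8,
                                  loss = "l2", seed = 9))
  expect_lt(tail(tr4$history$train_loss, 1), tr4$history$train_loss[1])
})

test_that("model checkpoints round-trip", {
  set.seed(6)
  n <- 8; N <- 20; M <- 10
  phi <- matrix(runif(n * N), n)
  X <- Matrix::Matrix(matrix(rbinom(n * M, 1, 0.3), n), sparse = TRUE)
  ds <- structure(list(phi = phi, phi_raw = phi, X = X,
                       meta = data.frame(id = 1:n),
                       splits = list(train = 1:6, val = 7:8,
                                     test = integer(0)),
                       samples = list(), config = dataset_config(seed = 1),
                       provenance = list(config_hash = "x")),
                  class = "blt_dataset")
  spec <- model_spec(list(list(out_ch = 2, kernel = 3, stride = 2),
                          list(out_ch = 2, kernel = 3, stride = 2),
                          list(out_ch = 2, kernel = 2, stride = 2)))
  tr <- train_model(build_1dcnn(N, M, spec, seed = 1), ds,
                    train_config(epochs = 3, batch_size = 4))
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(tr, path)
  back <- load_model(path)
  expect_identical(back$model$layers, tr$model$layers)
  expect_equal(predict(back, phi[1, ]), predict(tr, phi[1, ]))
})

test_that("a memorized tiny phantom is reconstructed to within the node
           spacing", {
  rep <- memo_eval()
  sm <- rep$summary
  le <- sm$mean[sm$group == "single" & sm$metric == "le"]
  expect_lt(le, 1)  # below one edge length
  # report means are recomputable from the per-sample table
  ps <- rep$per_sample
  expect_equal(le, mean(ps$le[ps$type == "single"], na.rm = TRUE))
  d <- sm$mean[sm$group == "dual" & sm$metric == "dice"]
  expect_equal(d, mean(ps$dice[ps$type == "dual"]))
})
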