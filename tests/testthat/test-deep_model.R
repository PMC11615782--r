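# shared tiny fixture: m = 4 OTUs, d = 2 embeddings, n = 30 samples
tiny_fixture <- function(n = 30, seed = 1) {
  set.seed(seed)
  X <- matrix(rpois(4 * n, 4) + 1, 4, n,
              dimnames = list(paste0("o", 1:4), paste0("s", 1:n)))
  E <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("o", 1:4), c("PC1", "PC2")))
  emb <- structure(list(X = E, explained_variance = c(1, 0.5)),
                   class = "pf_embedding")
  y <- rbinom(n, 1, 0.5)
  list(X = X, emb = emb, y = y)
}

test_that("abundance tower and fusion follow the forward equations", {
  cfg <- pf_config(m = 2, d = 2, h = 1, l = 1, activation = "identity",
                   task = "regression", dropout = 0, seed = 1)
  params <- pf_init_params(cfg)
  params$W1 <- matrix(c(1, -1), 1, 2)
  params$b1 <- 0.5
  params$Wc <- matrix(0, 2, 1)
  params$bc <- 1                      # f_P = 1: multiplicative identity
  params$Wo <- matrix(1, 1, 1)
  params$bo <- 0
  XA <- matrix(c(2, 1), 2, 1)
  cache <- phylofuse:::pf_forward(params, XA, list(1:2), diag(2), cfg)
  expect_equal(as.numeric(cache$fA), 1.5)          # W x + b by hand
  expect_equal(as.numeric(cache$fP), 1)
  expect_equal(as.numeric(cache$pred), 1.5)

  # zero abundance weights -> prediction is the head bias alone
  params$W1[] <- 0; params$b1 <- 0
  params$bo <- 3
  cache0 <- phylofuse:::pf_forward(params, XA, list(1:2), diag(2), cfg)
  expect_equal(as.numeric(cache0$pred), 3)

  # ReLU tower output is nonnegative
  cfg_r <- pf_config(m = 2, d = 2, h = 3, l = 1, activation = "relu",
                     dropout = 0, seed = 2)
  pr <- pf_init_params(cfg_r)
  cr <- phylofuse:::pf_forward(pr, matrix(rnorm(2), 2, 1), list(1:2),
                               diag(2), cfg_r)
  expect_true(all(cr$fA >= 0))
})

test_that("phylo tower implements valid convolution with max pooling", {
  # l = 1, one filter picking embedding column 1: f_P = max of column values
  E <- matrix(c(0.2, -1.0, 0.7, 0, 0, 0), 3, 2)
  cfg <- pf_config(m = 3, d = 2, h = 1, l = 1, activation = "identity",
                   dropout = 0, seed = 1)
  Wc <- matrix(c(1, 0), 2, 1)     # unit vector on column 1
  cv <- phylofuse:::conv_forward(E, list(1:3), Wc, 0, 1L, 0L)
  expect_equal(as.numeric(cv$fP), 0.7)
  expect_equal(as.numeric(cv$amax), 3L)

  # 3 present OTUs, l = 2: valid convolution gives 2 windows
  cfg2 <- pf_config(m = 3, d = 2, h = 1, l = 2, activation = "identity",
                    dropout = 0, seed = 1)
  Wc2 <- matrix(rnorm(4), 4, 1)
  cv2 <- phylofuse:::conv_forward(E, list(1:3), Wc2, 0, 2L, 0L)
  expect_true(cv2$amax[1, 1] %in% 1:2)   # only windows 1..(3 - 2 + 1)

  # order sensitivity: permuting rows changes f_P for l = 2 in general,
  # but never for l = 1 (max is order-free)
  perm <- c(2L, 3L, 1L)
  cv1p <- phylofuse:::conv_forward(E, list(perm), Wc, 0, 1L, 0L)
  expect_equal(cv1p$fP, cv$fP)

  # fewer present OTUs than l: zero-padded to one window
  cv3 <- phylofuse:::conv_forward(E, list(1L), Wc2, 0, 2L, 0L)
  expect_identical(dim(cv3$fP), c(1L, 1L))
})

test_that("output head and loss match closed forms", {
  expect_equal(1 / (1 + exp(0)), 0.5)
  cfg <- pf_config(m = 2, d = 2, h = 2, l = 1, task = "binary",
                   dropout = 0, seed = 1)
  params <- pf_init_params(cfg)
  params$Wo[] <- 0
  params$bo <- log(3)
  cache <- phylofuse:::pf_forward(params, matrix(1, 2, 1), list(1:2),
                                  diag(2), cfg)
  expect_equal(as.numeric(cache$pred), 0.75)   # sigmoid(ln 3)

  # losses
  expect_equal(pf_loss(c(1, 2, 3), c(1, 2, 3), "regression"), 0)
  expect_equal(pf_loss(rep(0.5, 4), c(1, 0, 1, 0), "binary"), log(2),
               tolerance = 1e-12)
  expect_equal(pf_loss(0.75, 1, "binary"), -log(0.75), tolerance = 1e-12)
  # clamping: exact 0/1 probabilities do not produce Inf
  expect_true(is.finite(pf_loss(c(0, 1), c(1, 0), "binary")))

  # multilabel head: one probability per label, all in (0, 1)
  cfg_m <- pf_config(m = 4, d = 2, h = 2, l = 1, task = "multilabel",
                     n_labels = 4, dropout = 0, seed = 3)
  pm <- pf_init_params(cfg_m)
  cm <- phylofuse:::pf_forward(pm, matrix(rnorm(4), 4, 1), list(1:4),
                               matrix(rnorm(8), 4, 2), cfg_m)
  expect_identical(dim(cm$pred), c(4L, 1L))
  expect_true(all(cm$pred > 0 & cm$pred < 1))
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(42)
  m <- 6; d <- 3; h <- 2; l <- 2; B <- 4
  for (task in c("binary", "regression")) {
    cfg <- pf_config(m = m, d = d, h = h, l = l, task = task, dropout = 0,
                     seed = 3)
    params <- pf_init_params(cfg)
    E <- matrix(rnorm(m * d), m, d)
    XA <- matrix(abs(rnorm(m * B)), m, B)
    XA <- sweep(XA, 2, colSums(XA), `/`)
    idx <- list(c(1L, 3L, 5L, 6L), c(2L, 4L), 1:6, c(2L, 3L, 4L))
    Y <- matrix(c(1, 0, 1, 0), 1)
    lossfun <- function(theta) {
      p <- phylofuse:::pf_unflatten(theta, params)
      cache <- phylofuse:::pf_forward(p, XA, idx, E, cfg)
      pf_loss(cache$pred, Y, cfg$task)
    }
    cache <- phylofuse:::pf_forward(params, XA, idx, E, cfg)
    grads <- phylofuse:::pf_backward(params, cache, XA, idx, E, Y, cfg)
    theta <- phylofuse:::pf_flatten(params)
    g_ana <- phylofuse:::pf_flatten(grads[names(params)])
    g_num <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + 1e-6
      tm <- theta; tm[i] <- tm[i] - 1e-6
      (lossfun(tp) - lossfun(tm)) / 2e-6
    }, numeric(1))
    rel <- abs(g_ana - g_num) / pmax(1e-8, abs(g_ana) + abs(g_num))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training is seeded-deterministic and respects regularization", {
  fx <- tiny_fixture()
  data <- pf_data(fx$X, fx$emb, fx$y)
  cfg <- pf_config(m = 4, d = 2, h = 4, l = 2, task = "binary",
                   max_epochs = 15, patience = 5, seed = 11)
  m1 <- pf_train(data, cfg, 1:20, 21:30)
  m2 <- pf_train(data, cfg, 1:20, 21:30)
  expect_identical(m1$report, m2$report)
  expect_identical(m1$params, m2$params)

  # huge weight decay shrinks weights toward zero; predictions collapse
  cfg_wd <- pf_config(m = 4, d = 2, h = 4, l = 2, task = "binary",
                      weight_decay = 1e3, max_epochs = 30, patience = 30,
                      seed = 11)
  m_wd <- pf_train(data, cfg_wd, 1:20, 21:30)
  expect_lt(max(abs(m_wd$params$W1)), 1e-3)
  preds <- predict(m_wd, data, 21:30)
  expect_lt(diff(range(preds)), 0.02)

  expect_error(pf_train(data, cfg, integer(0), 21:30), "empty training")
  expect_error(pf_train(data, cfg, 1:20, 20:30), "overlap")
})

test_that("split_dataset honors ratios, stratification, and partitions", {
  sp <- split_dataset(100, c(68, 12, 20), seed = 1)
  expect_identical(lengths(sp), c(train = 68L, val = 12L, test = 20L))
  sp2 <- split_dataset(400, c(50, 25, 25), seed = 2)
  expect_identical(lengths(sp2), c(train = 200L, val = 100L, test = 100L))
  all_idx <- sort(unlist(sp2, use.names = FALSE))
  expect_identical(all_idx, 1:400)

  # stratification keeps class balance in every set
  labs <- rep(c(0, 1), c(100, 300))
  sp3 <- split_dataset(400, c(50, 25, 25), stratify_labels = labs, seed = 3)
  for (part in sp3) {
    expect_lt(abs(mean(labs[part]) - 0.75), 0.05)
  }
  expect_identical(sort(unlist(sp3, use.names = FALSE)), 1:400)

  expect_error(split_dataset(100, c(60, 20, 10)), "100")
  expect_error(split_dataset(3, c(68, 12, 20)), "empty")

  # determinism
  expect_identical(split_dataset(50, seed = 9), split_dataset(50, seed = 9))
})

test_that("lodo_folds gives one complementary fold per study", {
  ids <- rep(paste0("study", 1:15), times = sample(5:10, 15, replace = TRUE))
  folds <- lodo_folds(ids)
  expect_length(folds, 15)
  tested <- sort(unlist(lapply(folds, `[[`, "test"), use.names = FALSE))
  expect_identical(tested, seq_along(ids))   # each sample tested exactly once
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), seq_along(ids))
  }

  two <- lodo_folds(c("a", "a", "b"))
  expect_identical(two$a$test, 1:2)
  expect_identical(two$b$train, 1:2)
  expect_error(lodo_folds(rep("a", 5)), ">= 2")
})

test_that("baseline mode reduces the model to the abundance tower", {
  fx <- tiny_fixture()
  data <- pf_data(fx$X, fx$emb, fx$y)
  cfg <- pf_config(m = 4, d = 2, h = 4, l = 2, task = "binary",
                   max_epochs = 5, patience = 5, seed = 5, use_phylo = FALSE)
  params <- pf_init_params(cfg)
  cache <- phylofuse:::pf_forward(params, data$XA[, 1:3], data$idx_list[1:3],
                                  data$E, cfg)
  expect_equal(cache$fP, matrix(1, 4, 3))     # f_P forced to ones
  expect_equal(cache$f, cache$fA)
  m <- pf_train(data, cfg, 1:20, 21:30)
  expect_s3_class(m, "pf_model")
})
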