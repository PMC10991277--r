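# Small configurations keep these training runs in seconds; the full-scale
# planted-signal study lives in test-acceptance.R.

tiny_cfg <- function(max_epochs = 6L, ...) {
  modelConfig(kernel_size = 4L, n_neurons = 6L, max_epochs = max_epochs,
              normalize_labels = TRUE, seed = 99L, ...)
}

test_that("model shapes follow the config and builds are seed-deterministic", {
  cfg <- modelConfig(kernel_size = 18L, n_neurons = 256L)
  m <- buildModel(cfg, L_max = 150L)
  expect_equal(dim(m@weights$W1), c(18L * 20L, 256L))  # 256 filters of width 18
  m2 <- buildModel(cfg, L_max = 150L)
  expect_identical(m@weights, m2@weights)
})

test_that("parameter count matches the closed-form layer tally", {
  cfg <- modelConfig(kernel_size = 3L, n_neurons = 4L)
  L <- 40L
  m <- buildModel(cfg, L_max = L)
  # independent shape arithmetic: conv valid lengths and pooled sizes
  k <- 3; Fn <- 4; H <- 4; pool <- 2
  P1 <- L - k + 1          # 38
  P2 <- P1 %/% pool        # 19
  P3 <- P2 - k + 1         # 17
  P4 <- P3 %/% pool        # 8
  expected <- (k * 20 * Fn + Fn) + (k * Fn * Fn + Fn) +
    (P4 * Fn * H + H) + (H * H + H) + (H + 1)
  expect_equal(countParams(m), expected)
})

test_that("too-short inputs are rejected with the minimum length", {
  cfg <- modelConfig(kernel_size = 18L, n_neurons = 8L)
  expect_error(buildModel(cfg, L_max = 30L), "minimum input length")
})

test_that("gradients match numerical differentiation", {
  cfg <- modelConfig(kernel_size = 3L, n_neurons = 4L, seed = 3L)
  L <- 20L
  m <- buildModel(cfg, L_max = L)
  # nudge biases off zero so no pre-activation sits exactly on a ReLU kink
  set.seed(31)
  w <- lapply(m@weights, function(x) x + rnorm(length(x), sd = 0.05))
  n <- 4L
  seqs <- vapply(1:n, function(i)
    paste(sample(c(OGTpred:::AA_ALPHABET20, "X"), L, TRUE), collapse = ""), "")
  names(seqs) <- paste0("p", 1:n)
  X <- aperm(encodeBatch(seqs, L_max = L), c(2, 3, 1))
  y <- rnorm(n, 50, 10)
  H <- cfg@n_neurons
  D1 <- matrix(rbinom(n * H, 1, 0.7), n, H) / 0.7
  D2 <- matrix(rbinom(n * H, 1, 0.7), n, H) / 0.7
  res <- OGTpred:::cnn_grad_cpp(X, y, w, 3L, 2L, D1, D2)
  loss_at <- function(w) OGTpred:::cnn_grad_cpp(X, y, w, 3L, 2L, D1, D2)$loss
  eps <- 1e-6
  for (nm in names(w)) {
    g <- res$grads[[nm]]
    picks <- unique(round(seq(1, length(w[[nm]]), length.out = 4)))
    for (j in picks) {
      wp <- w; wp[[nm]][j] <- wp[[nm]][j] + eps
      wm <- w; wm[[nm]][j] <- wm[[nm]][j] - eps
      gn <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_lt(abs(gn - g[j]), 1e-4 * max(1, abs(gn)))
    }
  }
})

test_that("training reduces the loss on a compositional signal", {
  gen <- small_generated()
  info <- proteinInfo(gen$corpus)
  ids <- info$protein_id
  set.seed(1)
  val <- sample(ids, 30)
  tr <- setdiff(ids, val)
  cfg <- tiny_cfg(max_epochs = 8L)
  m <- trainModel(buildModel(cfg, 60L), gen$corpus, tr, val)
  h <- trainingHistory(m)
  expect_gt(nrow(h), 2)
  # loss trends downward over the first epochs
  expect_lt(mean(tail(h$train_loss, 2)), h$train_loss[1])
  expect_true(m@trained)
})

test_that("constant labels trigger early stopping before max_epochs", {
  genome_tbl <- data.frame(genome_id = "gT", species = "sp", ogt_celsius = 60)
  set.seed(5)
  prot <- data.frame(
    protein_id = sprintf("gT|p%02d", 1:40), genome_id = "gT",
    sequence = vapply(1:40, function(i)
      paste(sample(OGTpred:::AA_ALPHABET20, 50, TRUE), collapse = ""), ""))
  corpus <- OGTpred:::makeCorpus(genome_tbl, prot)
  # fast-converging settings so the validation plateau is reached quickly
  cfg <- modelConfig(kernel_size = 4L, n_neurons = 4L, max_epochs = 50L,
                     early_stop_patience = 3L, normalize_labels = TRUE,
                     learning_rate = 0.05, batch_size = 8L, seed = 2L)
  m <- trainModel(buildModel(cfg, 50L), corpus,
                  sprintf("gT|p%02d", 1:30), sprintf("gT|p%02d", 31:40))
  expect_lt(m@stopped_epoch, 50L)
})

test_that("training is reproducible from the seed", {
  gen <- small_generated()
  info <- proteinInfo(gen$corpus)
  set.seed(2)
  val <- sample(info$protein_id, 20)
  tr <- sample(setdiff(info$protein_id, val), 60)
  cfg <- tiny_cfg(max_epochs = 3L)
  m1 <- trainModel(buildModel(cfg, 60L), gen$corpus, tr, val)
  m2 <- trainModel(buildModel(cfg, 60L), gen$corpus, tr, val)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@stopped_epoch, m2@stopped_epoch)
})

test_that("prediction is batch-invariant, duplicate-consistent and serialisable", {
  gen <- small_generated()
  info <- proteinInfo(gen$corpus)
  set.seed(3)
  val <- sample(info$protein_id, 15)
  tr <- setdiff(info$protein_id, val)
  m <- trainModel(buildModel(tiny_cfg(max_epochs = 2L), 60L), gen$corpus, tr, val)
  seqs <- OGTpred:::asSequenceVector(gen$corpus)[val[1:6]]
  batch <- predictOptTemp(m, seqs)
  single <- vapply(seq_along(seqs), function(i)
    unname(predictOptTemp(m, seqs[i])), 0)
  expect_equal(unname(batch), single, tolerance = 1e-5)
  dup <- predictOptTemp(m, stats::setNames(rep(seqs[1], 2), c("a", "b")))
  expect_equal(dup[["a"]], dup[["b"]])
  # checkpoint round-trip
  p <- tempfile(fileext = ".ckpt")
  saveModel(m, p)
  m2 <- loadModel(p)
  expect_equal(predictOptTemp(m2, seqs), batch)
  # schema guard
  bad <- readRDS(p); bad$schema <- "other/9"; saveRDS(bad, p)
  expect_error(loadModel(p), "schema")
})

test_that("pre-encoded batches must match the model's input length", {
  m <- buildModel(tiny_cfg(), 60L)
  arr <- encodeBatch(c(a = "ACDEF"), L_max = 70L)
  expect_error(predictOptTemp(m, arr), "L_max")
})

test_that("grid search scores pairs and applies the tie rule", {
  gen <- small_generated()
  info <- proteinInfo(gen$corpus)
  set.seed(4)
  val <- sample(info$protein_id, 25)
  tr <- setdiff(info$protein_id, val)
  tpl <- tiny_cfg(max_epochs = 2L)
  gs <- gridSearch(gen$corpus, tr, val, kernel_sizes = c(5L, 4L),
                   n_neurons = 4L, template = tpl, L_max = 60L)
  expect_equal(nrow(gs@tried), 2L)
  ok <- gs@tried[gs@tried$status == "ok", ]
  expect_equal(max(ok$validation_r),
               ok$validation_r[ok$kernel_size == gs@best@kernel_size &
                               ok$n_neurons == gs@best@n_neurons])
  # single candidate: trivially best
  gs1 <- gridSearch(gen$corpus, tr, val, 4L, 4L, template = tpl, L_max = 60L)
  expect_equal(gs1@best@kernel_size, 4L)
  expect_equal(gs1@best@n_neurons, 4L)
  # explicit tie (duplicated correlation by duplicated pair) -> smaller kernel
  tried <- data.frame(kernel_size = c(6L, 3L), n_neurons = c(4L, 4L),
                      validation_r = c(0.5, 0.5), status = "ok")
  ord <- order(-tried$validation_r, tried$kernel_size, tried$n_neurons)
  expect_equal(tried$kernel_size[ord[1]], 3L)
})
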