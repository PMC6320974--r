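test_that("input corruption zeroes the expected fraction of entries", {
  set.seed(1)
  x <- matrix(runif(100, 0.5, 1), 10)
  expect_identical(corrupt(x, 0), x)
  expect_equal(corrupt(x, 1), x * 0)
  big <- matrix(1, 100, 100)
  set.seed(2)
  frac <- mean(corrupt(big, 0.3) == 0)
  expect_lt(abs(frac - 0.3), 0.02)
  # surviving entries are unchanged
  set.seed(3)
  cx <- corrupt(x, 0.4)
  expect_true(all(cx == 0 | cx == x))
})

test_that("sdae_loss reproduces the three-term hand example and reduces correctly", {
  x <- rbind(c(1, 0), c(0, 1))
  x_hat <- x * 0
  E <- rbind(c(1, 0), c(0, 0))
  S <- matrix(0, 2, 2); S[1, 2] <- 0.5
  # L1 = 2, L2 = 0.5 * ||(1,0)-(0,0)||^2 = 0.5, beta = 0
  expect_equal(sdae_loss(x, x_hat, E, S, alpha = 1, beta = 0), 2.5)
  # alpha = beta = 0 -> pure reconstruction
  expect_equal(sdae_loss(x, x_hat, E, S, alpha = 0, beta = 0), 2)
  # perfect reconstruction + identical embeddings -> beta * Lreg only
  W <- list(matrix(2, 2, 2))
  expect_equal(sdae_loss(x, x, rbind(c(1, 1), c(1, 1)), S, weights = W,
                         alpha = 1, beta = 0.5), 0.5 * 16)
  expect_error(sdae_loss(x, x_hat[1, , drop = FALSE], E, S), "shape")
})

test_that("pairwise supervision sum equals its Laplacian-form evaluation", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:10, 1); d <- sample(2:5, 1)
    E <- matrix(rnorm(n * d), n)
    S <- matrix(runif(n * n), n)
    S <- (S + t(S)) / 2          # symmetric case: 2 tr(E' L E)
    L <- diag(rowSums(S)) - S
    expect_equal(hinadr:::.supervision_l2(E, S), 2 * sum(diag(t(E) %*% L %*% E)),
                 tolerance = 1e-8)
    expect_equal(hinadr:::.supervision_l2(E, S), supervision_pairwise(E, S),
                 tolerance = 1e-8)
  }
})

test_that("training reduces the loss and is reproducible from the seed", {
  S <- random_proximity(30, seed = 4)
  cfg <- sdae_config(layer_dims = c(16, 8), epochs = 80, seed = 99)
  emb <- train_subnetwork_embedding(S, cfg)
  expect_equal(dim(emb$E), c(30L, 8L))
  log <- attr(emb, "training_log")
  expect_lt(log$total[nrow(log)], log$total[1])
  # transient upticks stay within the adaptive-optimizer allowance
  ratios <- log$total[-1] / log$total[-nrow(log)]
  expect_true(all(ratios <= 1.05))
  # bitwise determinism under a fixed seed
  emb2 <- train_subnetwork_embedding(S, cfg)
  expect_identical(emb$E, emb2$E)
  # a different seed moves the solution
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(train_subnetwork_embedding(S, cfg2)$E, emb$E))
})

test_that("zero supervision weight leaves a plain denoising auto-encoder", {
  # with alpha = 0 the supervision gradient contributes nothing: training on
  # two different S matrices gives identical weights
  S1 <- random_proximity(12, seed = 5)
  S2 <- random_proximity(12, seed = 6)
  S2$S[] <- S2$S * 0.3
  cfg <- sdae_config(layer_dims = c(6, 3), alpha = 0, corruption_p = 0,
                     epochs = 30, seed = 7)
  e1 <- hinadr:::.train_sdae(S1$S, S1$S, cfg)
  e2 <- hinadr:::.train_sdae(S1$S, S2$S, cfg)
  expect_identical(e1$E, e2$E)
})

test_that("combine_supervision takes the alpha-weighted elementwise mean", {
  S1 <- matrix(c(0, 1, 1, 0), 2)
  S2 <- matrix(c(0, 0.4, 0.4, 0), 2)
  out <- combine_supervision(list(A = S1, B = S2), c(A = 0.2, B = 0.4))
  expect_equal(out, matrix(c(0, 0.6, 0.6, 0), 2))
  # equal weights -> plain mean; single meta-path -> passthrough
  expect_equal(combine_supervision(list(A = S1, B = S2), c(A = 1, B = 1)),
               (S1 + S2) / 2)
  expect_equal(combine_supervision(list(A = S1), c(A = 0.3)), S1)
  expect_error(combine_supervision(list(A = S1), c(B = 0.3)), "names")
})

test_that("the secondary encoder fuses embeddings and preserves proximity", {
  set.seed(11)
  # two-block structure so the combined proximity has clear top/bottom pairs
  n <- 24
  block <- rep(1:2, each = n / 2)
  S <- outer(block, block, function(a, b) ifelse(a == b, 0.9, 0.05))
  diag(S) <- 1
  rownames(S) <- colnames(S) <- sprintf("D%02d", 1:n)
  prox <- list(DCD = meta_path_proximity("DCD", S, normalized = TRUE),
               DPD = meta_path_proximity("DPD", S, normalized = TRUE))
  cfg <- sdae_config(layer_dims = c(16, 6), epochs = 150, seed = 2)
  E_list <- lapply(prox, train_subnetwork_embedding, cfg = cfg)
  int <- integration_config(sdae = sdae_config(layer_dims = c(16, 6),
                                               epochs = 150, seed = 3))
  eF <- train_final_embedding(E_list, prox, int)
  expect_equal(attr(eF, "concat_dim"), 12)
  expect_equal(dim(eF$E), c(n, 6L))
  log <- attr(eF, "training_log")
  expect_lt(log$total[nrow(log)], log$total[1])
  # top-decile proximity pairs end closer than bottom-decile pairs
  Sbar <- combine_supervision(prox, attr(eF, "alpha_p"))
  D2 <- as.matrix(dist(eF$E))
  ut <- upper.tri(Sbar)
  hi <- Sbar[ut] >= quantile(Sbar[ut], 0.9)
  lo <- Sbar[ut] <= quantile(Sbar[ut], 0.1)
  expect_lt(mean(D2[ut][hi]), mean(D2[ut][lo]))
  # inconsistent drug orders are rejected
  E_bad <- E_list
  E_bad$DCD$ids <- rev(E_bad$DCD$ids)
  expect_error(train_final_embedding(E_bad, prox, int), "orders")
})

test_that("weight search keeps the midpoint on ties and finds planted signal", {
  hin <- random_hin(n_drugs = 40, seed = 31)
  S1 <- random_proximity(40, seed = 32)
  # disabled search and single meta-path both return the 0.3 default
  expect_equal(grid_search_alpha(hin, list(DCD = S1), NULL,
                                 integration_config(grid_search = FALSE)),
               c(DCD = 0.3))
  expect_equal(grid_search_alpha(hin, list(DCD = S1), matrix(0:1, 40, 2),
                                 integration_config(grid_search = TRUE),
                                 seed = 1),
               c(DCD = 0.3))
  # planted signal: one informative proximity, two noise ones; over 5 seeds
  # the informative weight should not fall below the noise weights' median
  set.seed(77)
  cluster <- rep(0:1, each = 20)
  labels <- matrix(cluster, ncol = 1)
  S_sig <- outer(cluster, cluster, function(a, b) ifelse(a == b, 0.9, 0.1))
  diag(S_sig) <- 1
  rownames(S_sig) <- colnames(S_sig) <- hin$drugs   # satisfies symmetry
  sig <- meta_path_proximity("DPnD", S_sig, normalized = TRUE)
  wins <- 0
  for (s in 1:5) {
    S_list <- list(DPnD = sig,
                   DCD = random_proximity(40, seed = 100 + s),
                   DDID = random_proximity(40, seed = 200 + s, "DDID"))
    w <- grid_search_alpha(hin, S_list, labels,
                           integration_config(grid_search = TRUE,
                                              labeled_fraction = 0.5,
                                              folds = 5),
                           seed = s, sweeps = 1)
    if (w[["DPnD"]] >= median(w[c("DCD", "DDID")])) wins <- wins + 1
  }
  expect_gte(wins, 3)
})
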