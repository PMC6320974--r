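test_that("the two-stage split honors its arithmetic and is a partition", {
  for (n in c(100, 548)) {
    drugs <- sprintf("D%04d", seq_len(n))
    sp <- make_split(drugs, seed = 3)
    n_test <- floor(0.1 * n)
    n_val <- floor(0.05 * (n - n_test))
    expect_length(sp$test, n_test)
    expect_length(sp$validation, n_val)
    expect_length(sp$train, n - n_test - n_val)
    expect_length(intersect(sp$test, sp$train), 0)
    expect_length(intersect(sp$test, sp$validation), 0)
    expect_setequal(c(sp$test, sp$train, sp$validation), drugs)
  }
  # seeded: same seed reproduces, different seed differs
  d <- sprintf("D%03d", 1:100)
  expect_identical(make_split(d, seed = 1), make_split(d, seed = 1))
  expect_false(identical(make_split(d, seed = 1)$test,
                         make_split(d, seed = 2)$test))
})

test_that("scrubbing removes every ADR trace of test drugs from training inputs", {
  hin <- random_hin(n_drugs = 12, seed = 8)
  test_drugs <- hin$drugs[c(2, 5)]
  scrubbed <- scrub_hin(hin, test_drugs)
  expect_equal(sum(scrubbed$A_dd[test_drugs, ]), 0)
  expect_equal(sum(scrubbed$A_dd[, test_drugs]), 0)
  expect_equal(sum(scrubbed$M_dse[test_drugs, ]), 0)
  # non-test rows untouched
  keep <- setdiff(hin$drugs, test_drugs)
  expect_equal(as.matrix(scrubbed$M_dse[keep, ]), as.matrix(hin$M_dse[keep, ]))
  expect_equal(as.matrix(scrubbed$A_dd[keep, keep]),
               as.matrix(hin$A_dd[keep, keep]))
})

test_that("AP@K matches hand-worked values and the definitional oracle", {
  # relevant at ranks 1 and 3 with L = 2, K = 3 -> (1 + 2/3) / 2
  expect_equal(average_precision_at_k(c("a", "b", "c"), c("a", "c"), 3),
               (1 + 2 / 3) / 2)
  # saturation and miss cases
  expect_equal(average_precision_at_k(letters[1:5], letters[1:3], 3), 1)
  expect_equal(average_precision_at_k(letters[1:5], "z", 5), 0)
  expect_warning(out <- average_precision_at_k(letters[1:3], character(), 3),
                 "relevant")
  expect_equal(out, 0)
  expect_error(average_precision_at_k(c("a", "a"), "a", 2), "duplicate")
  # exhaustive: all 720 orderings of 6 items, several relevant sets
  library(utils)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  all_perm <- perms(letters[1:6])
  expect_length(all_perm, 720)
  for (rel in list("a", c("a", "b"), c("b", "d", "f"), letters[1:6])) {
    for (k in c(2, 4, 6)) {
      for (p in all_perm[seq(1, 720, by = 13)]) {
        expect_equal(average_precision_at_k(p, rel, k),
                     ap_at_k_oracle(p, rel, k))
      }
    }
  }
  # the literal printed formula exceeds 1 on a perfect short list
  expect_gt(average_precision_at_k(c("a", "x", "y"), "a", 3,
                                   mode = "as_printed"), 1)
})

test_that("MAP@K averages AP over instances with relevant items", {
  r <- list(c("a", "b", "c"), c("x", "y", "z"))
  rel <- list("a", "q")       # AP 1 and 0
  expect_equal(map_at_k(r, rel, 3), 0.5)
  expect_equal(map_at_k(r[c(2, 1)], rel[c(2, 1)], 3), 0.5)  # order-invariant
  # instances with no relevant item are excluded from the mean
  rel2 <- list("a", character())
  expect_equal(map_at_k(r, rel2, 3), 1)
  expect_error(map_at_k(list(), list(), 3), "empty")
})

test_that("ROC-AUC equals the pairwise brute force, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  for (s in 1:8) {
    set.seed(s)
    n <- sample(10:100, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), roc_auc_bruteforce(scores, labels))
  }
  # null scores concentrate around 0.5
  set.seed(99)
  s <- runif(10000); y <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.02)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("run_protocol produces per-repetition rows, aggregates, and variants", {
  g <- generate_hin(synth_config(n_drugs = 40, n_chems = 20, n_prots = 40,
                                 n_ses = 12, n_dis = 8, n_clusters = 3,
                                 ddi_within_rate = 0.5, seed = 5))
  cfg <- protocol_config(repetitions = 2, mu = 0.9,
                         sdae = sdae_config(layer_dims = c(16, 8), epochs = 40),
                         integration = integration_config(
                           sdae = sdae_config(layer_dims = c(16, 8),
                                              epochs = 40)),
                         map_k = c(5, 10), seed = 11)
  rep1 <- run_protocol(g$hin, g$tasks, cfg)
  expect_equal(nrow(rep1$rows), 2 * 3)    # 2 repetitions x 3 tasks
  expect_setequal(unique(rep1$rows$task),
                  c("single_drug_se", "ddi_occurrence", "ddi_type"))
  expect_true(all(rep1$rows$ROC_AUC >= 0 & rep1$rows$ROC_AUC <= 1))
  expect_true(all(rep1$rows$MAP_5 >= 0 & rep1$rows$MAP_5 <= 1))
  expect_equal(nrow(rep1$aggregate), 3)
  # bit-for-bit reproducible from the master seed
  rep2 <- run_protocol(g$hin, g$tasks, cfg)
  expect_identical(rep1$rows, rep2$rows)
  # ablation variant is labeled and runs without the propagation meta-path
  cfg_abl <- cfg; cfg_abl$variant <- "no-target-propagation"
  cfg_abl$tasks <- "single_drug_se"
  rep3 <- run_protocol(g$hin, g$tasks, cfg_abl)
  expect_true(all(rep3$rows$variant == "no-target-propagation"))
})

test_that("no test-drug label leaks into training-side artifacts", {
  # poison the ADR labels of the would-be test drugs with sentinels and
  # check the scrubbed training HIN never carries them
  hin <- random_hin(n_drugs = 20, seed = 13)
  sp <- make_split(hin$drugs, seed = 7)
  poisoned <- hin
  idx <- match(sp$test, hin$drugs)
  poisoned$M_dse[idx, ] <- 1      # sentinel: all labels on
  poisoned$A_dd[idx, ] <- 0; poisoned$A_dd[, idx] <- 0
  poisoned$A_dd[idx[1], idx[2]] <- 1; poisoned$A_dd[idx[2], idx[1]] <- 1
  tr <- scrub_hin(poisoned, sp$test)
  expect_equal(sum(tr$M_dse[idx, ]), 0)
  expect_equal(sum(tr$A_dd[idx, ]), 0)
  # proximities built from the scrubbed HIN are sentinel-free:
  # the poisoned test drugs have zero DSED/DD similarity to everyone
  S <- build_subnetworks(tr, mu = 0.9)
  expect_equal(sum(S$DSED$S[idx, setdiff(seq_along(hin$drugs), idx)]), 0)
  expect_equal(sum(S$DD$S[idx, ]), 0)
})
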