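#' Drug-level train/validation/test split
#'
#' Two-stage seeded partition: `floor(test * n)` drugs form the test set; of
#' the remainder, `floor(validation_share * n_rest)` form the validation set
#' (with `validation_share` read from `fractions["validation"]` as the share
#' of the *remainder*, 5% by default) and the rest the training set. So for
#' 100 drugs the 10% / 95-5% scheme yields 10 / 86 / 4.
#'
#' @param drugs character vector of drug IDs.
#' @param fractions named vector `c(test = 0.1, validation = 0.05)`.
#' @param seed RNG seed.
#' @return a `split_plan` with `test`, `train`, `validation` ID vectors plus
#'   `seed`.
#' @export
make_split <- function(drugs, fractions = c(test = 0.1, validation = 0.05),
                       seed = 1L) {
  n <- length(drugs)
  ft <- fractions[["test"]]; fv <- fractions[["validation"]]
  stopifnot(ft > 0, ft < 1, fv >= 0, fv < 1)
  n_test <- floor(ft * n)
  if (n_test < 1 || n_test >= n) .stopf("too few drugs (%d) for the split", n)
  set.seed(seed)
  test <- sort(sample(drugs, n_test))
  rest <- setdiff(drugs, test)
  n_val <- floor(fv * length(rest))
  validation <- if (n_val > 0) sort(sample(rest, n_val)) else character()
  train <- sort(setdiff(rest, validation))
  if (!length(train)) .stopf("empty training set")
  structure(list(test = test, train = train, validation = validation,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Scrub test drugs' labels from a training HIN
#'
#' Sets all drug-drug interaction rows/columns and all side-effect rows of
#' the test drugs to 0, so no training-side artifact (proximity, embedding,
#' head) can read a test drug's ADR labels.
#'
#' @param hin a `drug_hin`.
#' @param test_drugs drug IDs to scrub.
#' @return a new validated `drug_hin`.
#' @export
scrub_hin <- function(hin, test_drugs) {
  idx <- match(test_drugs, hin$drugs)
  if (anyNA(idx)) .stopf("unknown test drug: %s", test_drugs[which(is.na(idx))[1]])
  A <- hin$A_dd
  A[idx, ] <- 0
  A[, idx] <- 0
  Mse <- hin$M_dse
  Mse[idx, ] <- 0
  drug_hin(hin$drugs, hin$chems, hin$prots, hin$ses, hin$dis,
           Matrix::drop0(A), hin$M_dc, hin$M_dp, Matrix::drop0(Mse),
           hin$M_ddi, hin$A_pp)
}

#' Average precision at K
#'
#' Default (`mode = "standard"`):
#' `AP@K = sum_{k<=K} Precision(k) * rel(k) / min(L, K)` with `rel(k) = 1`
#' iff the item at rank `k` is relevant and `L` the number of relevant items;
#' values lie in `[0, 1]`. `mode = "as_printed"` sums `Precision(k)` over all
#' `k <= K` regardless of relevance (that reading can exceed 1 for perfect
#' rankings and is provided for comparison).
#'
#' @param ranking vector of item IDs in decreasing score order (no
#'   duplicates).
#' @param relevant set of relevant item IDs.
#' @param k cutoff (capped at the ranking length).
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @return scalar AP@K; 0 with a warning when `L = 0`.
#' @export
average_precision_at_k <- function(ranking, relevant, k,
                                   mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  if (anyDuplicated(ranking)) .stopf("duplicate items in ranking")
  L <- length(relevant)
  if (L == 0) {
    warning("no relevant items; AP@K = 0", call. = FALSE)
    return(0)
  }
  k <- min(k, length(ranking))
  rel <- as.numeric(ranking[seq_len(k)] %in% relevant)
  prec <- cumsum(rel) / seq_len(k)
  if (mode == "standard") sum(prec * rel) / min(L, k) else sum(prec) / min(L, k)
}

#' Mean average precision at K
#'
#' Unweighted mean of [average_precision_at_k()] over test instances;
#' instances without any relevant item are excluded from the mean.
#'
#' @param rankings list of ranked item-ID vectors.
#' @param relevants list of relevant-item sets, aligned with `rankings`.
#' @param k cutoff.
#' @param mode passed to [average_precision_at_k()].
#' @return scalar MAP@K.
#' @export
map_at_k <- function(rankings, relevants, k, mode = "standard") {
  if (!length(rankings)) .stopf("empty test set")
  if (length(rankings) != length(relevants))
    .stopf("rankings and relevants must align")
  keep <- lengths(relevants) > 0
  if (!any(keep)) .stopf("no instance has a relevant item")
  ap <- mapply(function(r, rel) average_precision_at_k(r, rel, k, mode),
               rankings[keep], relevants[keep])
  mean(ap)
}

#' ROC-AUC via the Mann-Whitney statistic
#'
#' `U / (n_pos * n_neg)` with midrank tie handling; equals the probability
#' that a random positive outscores a random negative (ties counted half).
#'
#' @param scores numeric scores.
#' @param labels binary labels (both classes must be present).
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) .stopf("scores/labels length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) .stopf("both classes required for ROC-AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Protocol configuration
#'
#' @param repetitions independent repetitions of the split/train/test cycle
#'   (default 5 at desk scale; 30 matches the full protocol).
#' @param fractions split fractions, see [make_split()].
#' @param mu,method target-propagation kernel settings.
#' @param sdae per-sub-network [sdae_config()] (its seed is re-derived per
#'   repetition).
#' @param integration an [integration_config()] for the secondary encoder.
#' @param neg_ratio negatives per positive for the pair tasks (default 1).
#' @param lambda ridge weight of the prediction heads.
#' @param map_k cutoffs for MAP@K (default 20, 50, 100).
#' @param tasks subset of the three tasks to run.
#' @param variant `"full"` or `"no-target-propagation"` (drops the DPnD
#'   meta-path: the ablation without PPI propagation).
#' @param seed master seed; per-repetition and per-stage seeds are derived
#'   from it with [derive_seed()].
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(repetitions = 5,
                            fractions = c(test = 0.1, validation = 0.05),
                            mu = 0.98, method = "solve",
                            sdae = sdae_config(),
                            integration = integration_config(),
                            neg_ratio = 1, lambda = 1e-4,
                            map_k = c(20, 50, 100),
                            tasks = .TASKS,
                            variant = c("full", "no-target-propagation"),
                            seed = 1L) {
  variant <- match.arg(variant)
  tasks <- match.arg(tasks, .TASKS, several.ok = TRUE)
  structure(list(repetitions = as.integer(repetitions), fractions = fractions,
                 mu = mu, method = method, sdae = sdae,
                 integration = integration, neg_ratio = neg_ratio,
                 lambda = lambda, map_k = map_k, tasks = tasks,
                 variant = variant, seed = as.integer(seed)),
            class = "protocol_config")
}

# rank item ids by decreasing score, ties broken by item index (stable)
.rank_items <- function(scores, items) {
  items[order(-scores, seq_along(items))]
}

.metric_row <- function(task, variant, rep_idx, rankings, relevants,
                        auc_scores, auc_labels, map_k) {
  maps <- vapply(map_k, function(k) map_at_k(rankings, relevants, k), 0)
  row <- data.frame(task = task, variant = variant, repetition = rep_idx,
                    stringsAsFactors = FALSE)
  for (i in seq_along(map_k)) row[[paste0("MAP_", map_k[i])]] <- maps[i]
  row$ROC_AUC <- roc_auc(auc_scores, auc_labels)
  row
}

.eval_task1 <- function(eF, hin, split, cfg, rep_seed) {
  Y <- as.matrix(hin$M_dse)
  tr <- split$train
  head <- suppressWarnings(
    train_head(eF$E[tr, , drop = FALSE], Y[tr, , drop = FALSE],
               lambda = cfg$lambda, seed = rep_seed))
  scores <- predict_task(head, eF, split$test, "single_drug_se")
  rankings <- lapply(seq_along(split$test),
                     function(i) .rank_items(scores[i, ], hin$ses))
  relevants <- lapply(split$test, function(d) hin$ses[Y[d, ] == 1])
  .metric_row("single_drug_se", cfg$variant, NA, rankings, relevants,
              as.vector(scores), as.vector(Y[split$test, , drop = FALSE]),
              cfg$map_k)
}

.eval_task2 <- function(eF, hin, split, cfg, rep_seed) {
  A <- as.matrix(hin$A_dd)
  tr <- split$train
  tr_pairs <- all_drug_pairs(tr)
  tr_keys <- pair_key(tr_pairs[, 1], tr_pairs[, 2])
  pos <- tr_keys[A[tr_pairs] == 1]
  neg <- negative_sample(pos, tr_keys, ratio = cfg$neg_ratio,
                         seed = derive_seed(rep_seed, 21))
  inst <- split_pair_key(c(pos, neg))
  y <- c(rep(1, length(pos)), rep(0, length(neg)))
  feats <- rbind(pair_features(eF, inst),
                 pair_features(eF, inst[, 2:1, drop = FALSE]))
  head <- suppressWarnings(
    train_head(feats, c(y, y), lambda = cfg$lambda, seed = rep_seed))
  # rank candidate partners for each test drug
  others <- hin$drugs
  rankings <- list(); relevants <- list()
  seen <- character()
  auc_s <- numeric(); auc_y <- numeric()
  for (d in split$test) {
    cand <- setdiff(others, d)
    pm <- cbind(rep(d, length(cand)), cand)
    sc <- as.vector(predict_task(head, eF, pm, "ddi_occurrence"))
    rankings[[d]] <- .rank_items(sc, cand)
    relevants[[d]] <- cand[A[d, cand] == 1]
    keys <- pair_key(pm[, 1], pm[, 2])
    new <- !(keys %in% seen)          # count each unordered pair once in AUC
    seen <- c(seen, keys[new])
    auc_s <- c(auc_s, sc[new]); auc_y <- c(auc_y, A[pm][new])
  }
  .metric_row("ddi_occurrence", cfg$variant, NA, rankings, relevants,
              auc_s, auc_y, cfg$map_k)
}

.eval_task3 <- function(eF, hin, split, cfg, ddi_type, rep_seed) {
  keys <- pair_key(ddi_type$instances[, 1], ddi_type$instances[, 2])
  in_train <- ddi_type$instances[, 1] %in% split$train &
    ddi_type$instances[, 2] %in% split$train
  pos_inst <- ddi_type$instances[in_train, , drop = FALSE]
  pos_lab <- ddi_type$labels[in_train, , drop = FALSE]
  tr_pairs <- all_drug_pairs(split$train)
  tr_keys <- pair_key(tr_pairs[, 1], tr_pairs[, 2])
  neg_keys <- negative_sample(keys[in_train], tr_keys, ratio = cfg$neg_ratio,
                              seed = derive_seed(rep_seed, 31))
  neg_inst <- split_pair_key(neg_keys)
  inst <- rbind(pos_inst, neg_inst)
  lab <- rbind(pos_lab, matrix(0, nrow(neg_inst), ncol(pos_lab)))
  feats <- rbind(pair_features(eF, inst),
                 pair_features(eF, inst[, 2:1, drop = FALSE]))
  head <- suppressWarnings(
    train_head(feats, rbind(lab, lab), lambda = cfg$lambda, seed = rep_seed))
  # test pairs: typed interacting pairs touching a test drug
  touch <- (ddi_type$instances[, 1] %in% split$test |
              ddi_type$instances[, 2] %in% split$test) &
    rowSums(ddi_type$labels) > 0
  if (!any(touch)) .stopf("no typed test pairs in this repetition")
  te_inst <- ddi_type$instances[touch, , drop = FALSE]
  te_lab <- ddi_type$labels[touch, , drop = FALSE]
  scores <- predict_task(head, eF, te_inst, "ddi_type")
  types <- colnames(te_lab) %||% paste0("type_", seq_len(ncol(te_lab)))
  rankings <- lapply(seq_len(nrow(te_inst)),
                     function(i) .rank_items(scores[i, ], types))
  relevants <- lapply(seq_len(nrow(te_inst)), function(i) types[te_lab[i, ] == 1])
  .metric_row("ddi_type", cfg$variant, NA, rankings, relevants,
              as.vector(scores), as.vector(te_lab), cfg$map_k)
}

#' Embed a HIN: sub-network encoders plus the secondary encoder
#'
#' Convenience wrapper running [build_subnetworks()],
#' [train_subnetwork_embedding()] per meta-path and
#' [train_final_embedding()].
#'
#' @param hin a `drug_hin`.
#' @param cfg a `protocol_config` (its `variant` decides whether DPnD is
#'   included).
#' @param seed seed from which per-meta-path seeds are derived.
#' @return list with `S_list`, `E_list` and the final [embedding_matrix()]
#'   `eF`.
#' @export
embed_hin <- function(hin, cfg = protocol_config(), seed = cfg$seed) {
  S_list <- build_subnetworks(hin, mu = cfg$mu, method = cfg$method)
  if (cfg$variant == "no-target-propagation") S_list$DPnD <- NULL
  E_list <- list()
  for (i in seq_along(S_list)) {
    sc <- cfg$sdae
    sc$seed <- derive_seed(seed, 100 + i)
    E_list[[names(S_list)[i]]] <- train_subnetwork_embedding(S_list[[i]], sc)
  }
  int <- cfg$integration
  int$sdae$seed <- derive_seed(seed, 200)
  eF <- train_final_embedding(E_list, S_list, int)
  list(S_list = S_list, E_list = E_list, eF = eF)
}

#' Run the full evaluation protocol
#'
#' For each repetition: draw a drug-level split, scrub the test drugs' ADR
#' labels from the training HIN, compute meta-path proximities, train the
#' per-sub-network and secondary encoders, fit task heads on training drugs,
#' score test instances against the *original* labels, and report MAP@K and
#' ROC-AUC per task. Deterministic given the master seed.
#'
#' @param hin a `drug_hin` carrying the complete (unscrubbed) labels.
#' @param tasks_data optional list; element `ddi_type` (a [task_dataset()])
#'   enables the DDI-type task.
#' @param config a [protocol_config()].
#' @return an `adr_report`: list with `rows` (one row per repetition x task)
#'   and `aggregate` (mean and sd per task), plus the config.
#' @export
run_protocol <- function(hin, tasks_data = NULL, config = protocol_config()) {
  tasks <- config$tasks
  if ("ddi_type" %in% tasks && is.null(tasks_data$ddi_type)) {
    message("no ddi_type labels supplied; skipping that task")
    tasks <- setdiff(tasks, "ddi_type")
  }
  rows <- list()
  for (r in seq_len(config$repetitions)) {
    rs <- derive_seed(config$seed, r)
    split <- make_split(hin$drugs, config$fractions, seed = rs)
    hin_tr <- scrub_hin(hin, split$test)
    emb <- embed_hin(hin_tr, config, seed = rs)
    for (task in tasks) {
      row <- switch(task,
        single_drug_se = .eval_task1(emb$eF, hin, split, config, rs),
        ddi_occurrence = .eval_task2(emb$eF, hin, split, config, rs),
        ddi_type = .eval_task3(emb$eF, hin, split, config,
                               tasks_data$ddi_type, rs))
      row$repetition <- r
      rows[[length(rows) + 1]] <- row
    }
  }
  rows <- do.call(rbind, rows)
  mcols <- setdiff(names(rows), c("task", "variant", "repetition"))
  agg <- do.call(rbind, lapply(split(rows, rows$task), function(df) {
    out <- data.frame(task = df$task[1], variant = df$variant[1],
                      stringsAsFactors = FALSE)
    for (m in mcols) {
      out[[paste0(m, "_mean")]] <- mean(df[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(df[[m]])
    }
    out
  }))
  rownames(agg) <- NULL
  structure(list(rows = rows, aggregate = agg, config = config),
            class = "adr_report")
}

#' @exportS3Method base::print
print.adr_report <- function(x, ...) {
  cat(sprintf("adr_report: %d repetitions, variant '%s'\n",
              x$config$repetitions, x$config$variant))
  print(x$aggregate, digits = 4)
  invisible(x)
}
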