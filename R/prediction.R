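.TASKS <- c("single_drug_se", "ddi_occurrence", "ddi_type")

#' Construct a labeled task dataset
#'
#' One of the three ADR prediction tasks: `single_drug_se` (multi-label side
#' effects of one drug), `ddi_occurrence` (binary: does a drug pair
#' interact), `ddi_type` (multi-label interaction event types of a pair).
#'
#' @param task task identifier.
#' @param instances drug IDs (character vector) for the single-drug task, or
#'   a two-column character matrix of unordered drug pairs.
#' @param labels binary vector (ddi_occurrence) or binary matrix with one row
#'   per instance (multi-label tasks).
#' @param split optional named list with `train`, `validation`, `test` drug
#'   ID vectors (drug-level split).
#' @return a `task_dataset` object.
#' @export
task_dataset <- function(task, instances, labels, split = NULL) {
  task <- match.arg(task, .TASKS)
  labels <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1)
  if (!all(labels %in% c(0, 1))) .stopf("labels must be binary")
  n_inst <- if (is.matrix(instances)) nrow(instances) else length(instances)
  if (nrow(labels) != n_inst) .stopf("one label row per instance required")
  if (task == "single_drug_se") {
    if (is.matrix(instances)) .stopf("single_drug_se instances are drug IDs")
  } else {
    if (!is.matrix(instances) || ncol(instances) != 2)
      .stopf("%s instances are two-column drug pairs", task)
    if (any(instances[, 1] == instances[, 2]))
      .stopf("self-pairs are not valid DDI instances")
  }
  structure(list(task = task, instances = instances, labels = labels,
                 split = split),
            class = "task_dataset")
}

#' Pair feature vector: concatenated embeddings
#'
#' Features for a drug pair are the two embedding vectors side by side,
#' `[e_i || e_j]`; swapping the pair swaps the halves (training presents both
#' orders, prediction averages them, see [predict_task()]).
#'
#' @param emb an [embedding_matrix()].
#' @param pairs two-column character matrix of drug IDs (or a single pair as
#'   a length-2 vector).
#' @return numeric matrix, one row per pair, `2 d` columns.
#' @export
pair_features <- function(emb, pairs) {
  if (!is.matrix(pairs)) pairs <- matrix(pairs, ncol = 2)
  unknown <- setdiff(unique(as.vector(pairs)), emb$ids)
  if (length(unknown)) .stopf("unknown drug(s): %s",
                              paste(utils::head(unknown, 3), collapse = ", "))
  cbind(emb$E[pairs[, 1], , drop = FALSE], emb$E[pairs[, 2], , drop = FALSE])
}

#' Sample negative instances
#'
#' Uniform sample (without replacement) of `floor(ratio * |positives|)`
#' instances from `universe` excluding `positives`.
#'
#' @param positives character vector of positive instance keys.
#' @param universe character vector of all candidate instance keys.
#' @param ratio negatives per positive (default 1).
#' @param seed optional RNG seed for reproducible sampling.
#' @return character vector of negative keys, disjoint from `positives`.
#' @export
negative_sample <- function(positives, universe, ratio = 1, seed = NULL) {
  stopifnot(ratio > 0)
  if (!is.null(seed)) set.seed(seed)
  cand <- setdiff(universe, positives)
  n_neg <- floor(ratio * length(positives))
  if (n_neg > length(cand))
    .stopf("universe too small: need %d negatives, only %d candidates",
           n_neg, length(cand))
  sample(cand, n_neg)
}

#' Train a prediction head
#'
#' A fully-connected sigmoid layer `y' = sigmoid(W %*% e + b)` minimizing the
#' regularized cross-entropy
#' `sum(-y log y' - (1 - y) log(1 - y')) + lambda * ||W||_F^2` with
#' full-batch Adam. Multi-label matrices are trained jointly, which for this
#' single-layer head is equivalent to independent per-label logistic fits;
#' pass one column for the literal per-label protocol. The problem is convex
#' and the parameters start at zero, so the fit is deterministic.
#'
#' @param features numeric matrix, instances x d.
#' @param labels binary vector or matrix (instances x outputs).
#' @param lambda ridge weight on `W` (default 1e-4); bias unpenalized.
#' @param lr Adam step size.
#' @param epochs full-batch epochs.
#' @param seed kept for interface symmetry; the fit itself is deterministic.
#' @return a `task_head` with fields `W` (d x outputs), `b`, `lambda`.
#' @export
train_head <- function(features, labels, lambda = 1e-4, lr = 0.1,
                       epochs = 500, seed = 1L) {
  X <- as.matrix(features)
  Y <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1)
  if (!all(Y %in% c(0, 1))) .stopf("labels must be binary")
  if (nrow(X) != nrow(Y)) .stopf("features and labels disagree on instances")
  if (!all(is.finite(X))) .stopf("non-finite features")
  cm <- colMeans(Y)
  if (any(cm %in% c(0, 1)))
    warning(sprintf("%d output(s) have all-identical labels; fit proceeds",
                    sum(cm %in% c(0, 1))), call. = FALSE)
  d <- ncol(X); L <- ncol(Y)
  W <- matrix(0, d, L); b <- numeric(L)
  mW <- W; vW <- W; mb <- b; vb <- b
  for (t in seq_len(epochs)) {
    P <- sigmoid(sweep(X %*% W, 2, b, "+"))
    G <- P - Y
    gW <- t(X) %*% G + 2 * lambda * W
    gb <- colSums(G)
    u <- .adam_step(W, gW, mW, vW, t, lr); W <- u$theta; mW <- u$m; vW <- u$v
    u <- .adam_step(b, gb, mb, vb, t, lr); b <- u$theta; mb <- u$m; vb <- u$v
  }
  structure(list(W = W, b = b, lambda = lambda), class = "task_head")
}

#' Predict scores from a fitted head
#'
#' @param head a `task_head`.
#' @param features instances x d matrix.
#' @return matrix of probabilities in `(0, 1)`, instances x outputs.
#' @export
predict_head <- function(head, features) {
  X <- as.matrix(features)
  if (ncol(X) != nrow(head$W))
    .stopf("feature width %d != head input %d", ncol(X), nrow(head$W))
  sigmoid(sweep(X %*% head$W, 2, head$b, "+"))
}

#' Score task instances with a fitted head
#'
#' Single-drug instances are scored directly on their embedding rows. Pair
#' instances are scored in both orders and the two probabilities averaged, so
#' DDI scores are symmetric in the pair.
#'
#' @param head a `task_head`.
#' @param emb an [embedding_matrix()].
#' @param instances drug IDs (single-drug task) or two-column pair matrix.
#' @param task task identifier (see [task_dataset()]).
#' @return score matrix, instances x outputs.
#' @export
predict_task <- function(head, emb, instances, task) {
  task <- match.arg(task, .TASKS)
  if (task == "single_drug_se") {
    if (is.matrix(instances)) .stopf("single_drug_se takes drug IDs, not pairs")
    unknown <- setdiff(instances, emb$ids)
    if (length(unknown)) .stopf("unknown drug(s): %s", unknown[1])
    return(predict_head(head, emb$E[instances, , drop = FALSE]))
  }
  if (!is.matrix(instances) || ncol(instances) != 2)
    .stopf("%s takes a two-column pair matrix", task)
  if (any(instances[, 1] == instances[, 2]))
    .stopf("self-pairs are not valid DDI instances")
  s1 <- predict_head(head, pair_features(emb, instances))
  s2 <- predict_head(head, pair_features(emb, instances[, 2:1, drop = FALSE]))
  (s1 + s2) / 2
}
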