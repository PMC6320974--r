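#' Configuration for a semi-supervised stacked denoising auto-encoder
#'
#' All neurons use the sigmoid activation; training is full-batch Adam by
#' default (the drug axis is small). The loss is
#' `L1 + alpha * L2 + beta * Lreg` with `L1` the squared reconstruction error
#' of the clean input from its corrupted version, `L2` the proximity
#' supervision `sum_ij S[i,j] ||e_i - e_j||^2` and `Lreg` the Frobenius
#' penalty on all encoder/decoder weight matrices.
#'
#' @param layer_dims encoder hidden sizes ending at the embedding dimension
#'   `d` (default `c(256, 64)`; the decoder mirrors them back to the input).
#' @param corruption_p probability of zeroing each input neuron (default 0.2).
#' @param alpha weight of the proximity-supervision term (default 0.1). The
#'   supervision term alone is minimized by collapsing all embeddings to one
#'   point; the default keeps it a regularizer on top of reconstruction
#'   rather than the dominant force.
#' @param beta weight of the L2-norm weight regularizer (default 1e-4).
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs training epochs (default 200).
#' @param batch_mode `"full"` (default) or `"minibatch"`.
#' @param batch_size rows per minibatch (minibatch mode only).
#' @param seed RNG seed governing initialization and corruption noise.
#' @return an `sdae_config` list.
#' @export
sdae_config <- function(layer_dims = c(256, 64), corruption_p = 0.2,
                        alpha = 0.1, beta = 1e-4, learning_rate = 0.01,
                        epochs = 200, batch_mode = c("full", "minibatch"),
                        batch_size = NULL, seed = 1L) {
  batch_mode <- match.arg(batch_mode)
  stopifnot(length(layer_dims) >= 1, all(layer_dims >= 1),
            corruption_p >= 0, corruption_p <= 1,
            alpha >= 0, beta >= 0, learning_rate > 0, epochs >= 1)
  structure(list(layer_dims = as.integer(layer_dims),
                 corruption_p = corruption_p, alpha = alpha, beta = beta,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_mode = batch_mode, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "sdae_config")
}

#' Corrupt an input matrix by randomly zeroing entries
#'
#' Each entry is independently set to 0 with probability `p`; surviving
#' entries are unchanged. Draws from the current RNG stream.
#'
#' @param x numeric matrix.
#' @param p corruption probability in `[0, 1]`.
#' @return the corrupted matrix.
#' @export
corrupt <- function(x, p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return(x)
  if (p == 1) return(x * 0)
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x))
  x * mask
}

# L2 supervision term: literal ordered sum over (i, j) of S[i,j] ||e_i-e_j||^2,
# evaluated through the generalized Laplacian identity
#   sum_ij S_ij ||e_i - e_j||^2 = tr(E' (Dr + Dc - S - S') E)
# which reduces to 2 tr(E' L E), L = diag(S 1) - S, for symmetric S.
.supervision_l2 <- function(E, S) {
  rs <- rowSums(S); cs <- colSums(S)
  sum((rs + cs) * rowSums(E^2)) - 2 * sum(E * (S %*% E))
}

.supervision_grad_mat <- function(S) {
  # gradient of .supervision_l2 wrt E is 2 * Lgen %*% E
  diag(rowSums(S) + colSums(S)) - S - t(S)
}

#' Semi-supervised SDAE loss
#'
#' `L1 + alpha * L2 + beta * Lreg` with
#' `L1 = sum_i ||xhat_i - x_i||^2`,
#' `L2 = sum_{i,j} S[i,j] ||e_i - e_j||^2` and
#' `Lreg = sum_k (||W(k)||_F^2 + ||What(k)||_F^2)`.
#'
#' @param x clean input matrix (rows = drugs).
#' @param x_hat reconstruction.
#' @param E embedding matrix (rows = drugs).
#' @param S proximity supervision matrix.
#' @param weights list of weight matrices (encoder and decoder).
#' @param alpha,beta loss weights.
#' @return scalar loss.
#' @export
sdae_loss <- function(x, x_hat, E, S, weights = list(), alpha = 1,
                      beta = 1e-4) {
  if (!all(dim(x) == dim(x_hat))) .stopf("x and x_hat shapes differ")
  if (nrow(E) != nrow(x)) .stopf("E rows must match x rows")
  if (nrow(S) != nrow(E) || ncol(S) != nrow(E))
    .stopf("S must be n x n over the same drugs as E")
  L1 <- sum((x_hat - x)^2)
  L2 <- .supervision_l2(E, S)
  Lreg <- sum(vapply(weights, function(w) sum(w^2), 0))
  L1 + alpha * L2 + beta * Lreg
}

.init_params <- function(n_in, layer_dims) {
  dims_enc <- c(n_in, layer_dims)
  dims_dec <- c(rev(layer_dims), n_in)
  glorot <- function(fi, fo) {
    r <- sqrt(6 / (fi + fo))
    matrix(stats::runif(fi * fo, -r, r), fi, fo)
  }
  K <- length(layer_dims)
  W <- vector("list", K); b <- vector("list", K)
  Wd <- vector("list", K); bd <- vector("list", K)
  for (k in seq_len(K)) {
    W[[k]] <- glorot(dims_enc[k], dims_enc[k + 1])
    b[[k]] <- numeric(dims_enc[k + 1])
    Wd[[k]] <- glorot(dims_dec[k], dims_dec[k + 1])
    bd[[k]] <- numeric(dims_dec[k + 1])
  }
  list(W = W, b = b, Wd = Wd, bd = bd, K = K)
}

.sdae_forward <- function(params, X) {
  K <- params$K
  A <- vector("list", K + 1)
  A[[1]] <- X
  for (k in seq_len(K))
    A[[k + 1]] <- sigmoid(sweep(A[[k]] %*% params$W[[k]], 2, params$b[[k]], "+"))
  B <- vector("list", K + 1)
  B[[1]] <- A[[K + 1]]
  for (k in seq_len(K))
    B[[k + 1]] <- sigmoid(sweep(B[[k]] %*% params$Wd[[k]], 2, params$bd[[k]], "+"))
  list(A = A, B = B, E = A[[K + 1]], xhat = B[[K + 1]])
}

.adam_new <- function(params) {
  z <- function(p) lapply(p, function(m) m * 0)
  list(mW = z(params$W), vW = z(params$W), mb = z(params$b), vb = z(params$b),
       mWd = z(params$Wd), vWd = z(params$Wd), mbd = z(params$bd),
       vbd = z(params$bd), t = 0)
}

.adam_step <- function(theta, g, m, v, t, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# core trainer: X (n x m) input rows, S (n x n) proximity supervision
.train_sdae <- function(X, S, cfg) {
  set.seed(cfg$seed)
  n <- nrow(X); m <- ncol(X)
  params <- .init_params(m, cfg$layer_dims)
  K <- params$K
  st <- .adam_new(params)
  Lgen <- .supervision_grad_mat(S)     # dL2/dE = 2 * Lgen %*% E
  log <- matrix(NA_real_, cfg$epochs, 5,
                dimnames = list(NULL, c("epoch", "L1", "L2", "Lreg", "total")))
  batch <- cfg$batch_mode == "minibatch"
  bsize <- if (batch) min(cfg$batch_size %||% max(16L, n %/% 4L), n) else n

  for (ep in seq_len(cfg$epochs)) {
    idx <- if (batch) sort(sample.int(n, bsize)) else seq_len(n)
    Xb <- X[idx, , drop = FALSE]
    Xc <- corrupt(Xb, cfg$corruption_p)
    fw <- .sdae_forward(params, Xc)
    E <- fw$E
    # L2 on the batch; minibatch rescales by the inverse pair-sampling rate
    Sb <- S[idx, idx, drop = FALSE]
    l2scale <- (n / length(idx))^2
    L1 <- sum((fw$xhat - Xb)^2)
    L2 <- .supervision_l2(E, Sb) * l2scale
    Lreg <- sum(vapply(c(params$W, params$Wd), function(w) sum(w^2), 0))
    total <- L1 + cfg$alpha * L2 + cfg$beta * Lreg
    if (!is.finite(total))
      .stopf("non-finite SDAE loss at epoch %d (L1=%g, L2=%g, Lreg=%g); lower the learning rate",
             ep, L1, L2, Lreg)
    log[ep, ] <- c(ep, L1, L2, Lreg, total)

    # backward pass
    delta <- 2 * (fw$xhat - Xb) * fw$xhat * (1 - fw$xhat)
    gWd <- vector("list", K); gbd <- vector("list", K)
    for (k in rev(seq_len(K))) {
      gWd[[k]] <- t(fw$B[[k]]) %*% delta + 2 * cfg$beta * params$Wd[[k]]
      gbd[[k]] <- colSums(delta)
      delta <- (delta %*% t(params$Wd[[k]])) * fw$B[[k]] * (1 - fw$B[[k]])
    }
    # delta now carries dL/dE through the decoder incl. sigmoid'(z_E);
    # add the supervision gradient through the same activation
    Lg <- if (batch) .supervision_grad_mat(Sb) * l2scale else Lgen
    delta <- delta + cfg$alpha * (2 * (Lg %*% E)) * E * (1 - E)
    gW <- vector("list", K); gb <- vector("list", K)
    for (k in rev(seq_len(K))) {
      gW[[k]] <- t(fw$A[[k]]) %*% delta + 2 * cfg$beta * params$W[[k]]
      gb[[k]] <- colSums(delta)
      if (k > 1)
        delta <- (delta %*% t(params$W[[k]])) * fw$A[[k]] * (1 - fw$A[[k]])
    }

    st$t <- st$t + 1
    lr <- cfg$learning_rate
    for (k in seq_len(K)) {
      u <- .adam_step(params$W[[k]], gW[[k]], st$mW[[k]], st$vW[[k]], st$t, lr)
      params$W[[k]] <- u$theta; st$mW[[k]] <- u$m; st$vW[[k]] <- u$v
      u <- .adam_step(params$b[[k]], gb[[k]], st$mb[[k]], st$vb[[k]], st$t, lr)
      params$b[[k]] <- u$theta; st$mb[[k]] <- u$m; st$vb[[k]] <- u$v
      u <- .adam_step(params$Wd[[k]], gWd[[k]], st$mWd[[k]], st$vWd[[k]], st$t, lr)
      params$Wd[[k]] <- u$theta; st$mWd[[k]] <- u$m; st$vWd[[k]] <- u$v
      u <- .adam_step(params$bd[[k]], gbd[[k]], st$mbd[[k]], st$vbd[[k]], st$t, lr)
      params$bd[[k]] <- u$theta; st$mbd[[k]] <- u$m; st$vbd[[k]] <- u$v
    }
  }
  E <- .sdae_forward(params, X)$E      # clean pass for the final embedding
  list(E = E, params = params, log = as.data.frame(log))
}

#' Train a per-sub-network drug embedding
#'
#' Encodes one meta-path sub-network with a semi-supervised stacked denoising
#' auto-encoder: the input for drug `i` is row `i` of the (normalized)
#' proximity matrix, the supervision term pulls embeddings of high-proximity
#' drug pairs together, and the denoising corruption randomly zeroes input
#' neurons each epoch. Deterministic given `cfg$seed` (single-threaded BLAS).
#'
#' @param S_p a `meta_path_proximity` (normalized), or a plain symmetric
#'   matrix in `[0, 1]`.
#' @param cfg an [sdae_config()].
#' @return an [embedding_matrix()] tagged with the meta-path; the training
#'   log (epoch, L1, L2, Lreg, total) is attached as attribute
#'   `"training_log"`.
#' @export
train_subnetwork_embedding <- function(S_p, cfg = sdae_config()) {
  if (inherits(S_p, "meta_path_proximity")) {
    tag <- S_p$meta_path
    S <- S_p$S
  } else {
    tag <- "subnetwork"
    S <- as.matrix(S_p)
  }
  ids <- rownames(S) %||% paste0("drug_", seq_len(nrow(S)))
  fit <- .train_sdae(S, S, cfg)
  out <- embedding_matrix(ids, fit$E, source = tag)
  attr(out, "training_log") <- fit$log
  attr(out, "params") <- fit$params
  out
}

#' Combine per-meta-path proximities into one supervision matrix
#'
#' Weighted elementwise average
#' `S_bar = sum_p alpha(p) S(p) / sum_p alpha(p)`.
#'
#' @param S_list named list of `meta_path_proximity` objects (or matrices).
#' @param alpha_p named positive weights covering exactly `names(S_list)`.
#' @return the combined matrix.
#' @export
combine_supervision <- function(S_list, alpha_p) {
  mats <- lapply(S_list, function(s)
    if (inherits(s, "meta_path_proximity")) s$S else as.matrix(s))
  if (is.null(names(alpha_p)) || !setequal(names(alpha_p), names(S_list)))
    .stopf("alpha_p names must match S_list names exactly")
  if (any(alpha_p <= 0)) .stopf("meta-path weights must be positive")
  dims <- vapply(mats, dim, integer(2))
  if (any(dims != dims[, 1])) .stopf("proximity matrices differ in shape")
  acc <- mats[[1]] * 0
  for (p in names(mats)) acc <- acc + alpha_p[[p]] * mats[[p]]
  acc / sum(unlist(alpha_p))
}

#' Configuration for the secondary (integration) encoder
#'
#' @param alpha_p named meta-path weights for [combine_supervision()];
#'   `NULL` means uniform weights of 0.3 (the grid midpoint).
#' @param sdae an [sdae_config()] for the secondary encoder (input is the
#'   concatenation of per-meta-path embeddings; final dimension defaults
#'   to 64).
#' @param grid_search whether [grid_search_alpha()] should search the weights.
#' @param labeled_fraction fraction of drugs treated as labeled during the
#'   weight search (default 0.1).
#' @param folds cross-validation folds for the search (default 5).
#' @return an `integration_config` list.
#' @export
integration_config <- function(alpha_p = NULL,
                               sdae = sdae_config(layer_dims = c(256, 64)),
                               grid_search = FALSE, labeled_fraction = 0.1,
                               folds = 5) {
  stopifnot(labeled_fraction > 0, labeled_fraction <= 1, folds >= 2)
  if (!is.null(alpha_p) && any(unlist(alpha_p) <= 0))
    .stopf("alpha_p weights must be positive")
  structure(list(alpha_p = alpha_p, sdae = sdae, grid_search = grid_search,
                 labeled_fraction = labeled_fraction, folds = as.integer(folds)),
            class = "integration_config")
}

#' Train the final drug embedding with the secondary encoder
#'
#' Concatenates the per-meta-path embeddings into one vector per drug and
#' trains a second semi-supervised SDAE that reconstructs the concatenation
#' while preserving the weighted-average proximity
#' [combine_supervision()] across all sub-networks.
#'
#' @param E_list named list of [embedding_matrix()] objects sharing drug
#'   order (same meta-path names as `S_list`).
#' @param S_list named list of normalized `meta_path_proximity` objects.
#' @param int_cfg an [integration_config()].
#' @return an [embedding_matrix()] with `source = "final"`; attributes
#'   `"training_log"` and `"alpha_p"`.
#' @export
train_final_embedding <- function(E_list, S_list,
                                  int_cfg = integration_config()) {
  if (!setequal(names(E_list), names(S_list)))
    .stopf("E_list and S_list must cover the same meta-paths")
  E_list <- E_list[names(S_list)]
  ids <- E_list[[1]]$ids
  for (e in E_list)
    if (!identical(e$ids, ids)) .stopf("inconsistent drug orders across embeddings")
  X <- do.call(cbind, lapply(E_list, function(e) e$E))
  alpha_p <- int_cfg$alpha_p %||%
    stats::setNames(rep(0.3, length(S_list)), names(S_list))
  Sbar <- combine_supervision(S_list, alpha_p)
  fit <- .train_sdae(X, Sbar, int_cfg$sdae)
  out <- embedding_matrix(ids, fit$E, source = "final")
  attr(out, "training_log") <- fit$log
  attr(out, "alpha_p") <- alpha_p
  attr(out, "concat_dim") <- ncol(X)
  out
}

#' Grid search for the meta-path weights alpha(p)
#'
#' Coordinate ascent (2 sweeps, fixed meta-path order) over the grid
#' \{0.1, 0.2, 0.3, 0.4, 0.5\} per meta-path. Each candidate weight map is
#' scored by the mean cross-validated ROC-AUC of a ridge logistic head
#' trained on rows of the combined supervision matrix for a small labeled
#' drug subset; ties keep the incumbent weight, so with a single meta-path
#' (where every weight is equivalent by the normalization in
#' [combine_supervision()]) the grid midpoint 0.3 is returned.
#'
#' @param hin a `drug_hin` (supplies the drug registry).
#' @param S_list named list of normalized proximities.
#' @param labels binary matrix, drugs x outputs (e.g. side-effect labels).
#' @param int_cfg an [integration_config()]; `grid_search = FALSE` returns
#'   uniform weights 0.3 without searching.
#' @param seed RNG seed for the labeled subset and folds.
#' @param sweeps coordinate-ascent sweeps (default 2).
#' @return named numeric weight map over `names(S_list)`.
#' @export
grid_search_alpha <- function(hin, S_list, labels,
                              int_cfg = integration_config(grid_search = TRUE),
                              seed = 1L, sweeps = 2L) {
  paths <- names(S_list)
  uniform <- stats::setNames(rep(0.3, length(paths)), paths)
  if (!int_cfg$grid_search) return(uniform)
  labels <- as.matrix(labels)
  n <- length(hin$drugs)
  if (nrow(labels) != n) .stopf("labels must have one row per drug")
  set.seed(seed)
  n_lab <- max(int_cfg$folds, ceiling(int_cfg$labeled_fraction * n))
  if (n_lab > n) .stopf("fewer drugs than required labeled subset")
  lab_idx <- sort(sample.int(n, n_lab))
  fold_of <- stats::setNames(rep(seq_len(int_cfg$folds), length.out = n_lab)[
    sample.int(n_lab)], lab_idx)

  score_weights <- function(w) {
    Sbar <- combine_supervision(S_list, w)
    feats <- Sbar[lab_idx, , drop = FALSE]
    y <- labels[lab_idx, , drop = FALSE]
    scores <- y * NA_real_
    for (f in seq_len(int_cfg$folds)) {
      te <- which(fold_of == f)
      tr <- setdiff(seq_len(n_lab), te)
      if (!length(te) || !length(tr)) next
      head <- train_head(feats[tr, , drop = FALSE], y[tr, , drop = FALSE],
                         lambda = 1e-2, epochs = 150, seed = seed)
      scores[te, ] <- predict_head(head, feats[te, , drop = FALSE])
    }
    ok <- is.finite(scores)
    yy <- y[ok]; ss <- scores[ok]
    if (length(unique(yy)) < 2) return(0.5)
    roc_auc(ss, yy)
  }

  grid <- seq(0.1, 0.5, by = 0.1)
  w <- uniform
  best <- score_weights(w)
  for (s in seq_len(sweeps)) {
    for (p in paths) {
      for (v in grid) {
        if (v == w[[p]]) next
        cand <- w; cand[[p]] <- v
        sc <- score_weights(cand)
        if (sc > best + 1e-12) { w <- cand; best <- sc }
      }
    }
  }
  w
}
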