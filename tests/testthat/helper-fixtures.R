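# small hand-built HIN used across unit tests: 3 drugs, 3 substructures,
# 2 proteins (one PPI edge), 2 side effects, 2 diseases
tiny_hin <- function() {
  drugs <- c("d1", "d2", "d3")
  A_dd <- matrix(0, 3, 3)
  A_dd[1, 2] <- A_dd[2, 1] <- 1
  M_dc <- rbind(c(1, 1, 0),   # d1: c1, c2
                c(0, 1, 1),   # d2: c2, c3
                c(0, 0, 0))   # d3: none
  M_dp <- rbind(c(1, 0),      # d1 -> p1
                c(0, 1),      # d2 -> p2
                c(0, 0))      # d3: no targets
  M_dse <- rbind(c(1, 0), c(1, 1), c(0, 0))
  M_ddi <- rbind(c(1, 0), c(0, 0), c(0, 1))
  A_pp <- matrix(c(0, 1, 1, 0), 2)
  drug_hin(drugs, c("c1", "c2", "c3"), c("p1", "p2"), c("se1", "se2"),
           c("di1", "di2"), A_dd, M_dc, M_dp, M_dse, M_ddi, A_pp)
}

# random valid HIN for round-trip / invariant sweeps
random_hin <- function(n_drugs = 8, n_chems = 6, n_prots = 7, n_ses = 5,
                       n_dis = 4, density = 0.3, seed = 1) {
  set.seed(seed)
  rbin <- function(nr, nc) matrix(rbinom(nr * nc, 1, density), nr, nc)
  rsym <- function(n) {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    A[ut] <- rbinom(length(ut), 1, density)
    A + t(A)
  }
  drug_hin(sprintf("D%02d", 1:n_drugs), sprintf("C%02d", 1:n_chems),
           sprintf("P%02d", 1:n_prots), sprintf("S%02d", 1:n_ses),
           sprintf("I%02d", 1:n_dis),
           rsym(n_drugs), rbin(n_drugs, n_chems), rbin(n_drugs, n_prots),
           rbin(n_drugs, n_ses), rbin(n_drugs, n_dis), rsym(n_prots))
}

# brute-force PathSim: enumerate D-X-D path instances by looping over
# attribute nodes (independent of the matrix-product implementation)
pathsim_bruteforce <- function(M) {
  n <- nrow(M)
  count_paths <- function(i, j) {
    cnt <- 0
    for (x in seq_len(ncol(M))) if (M[i, x] == 1 && M[j, x] == 1) cnt <- cnt + 1
    cnt
  }
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    den <- count_paths(i, i) + count_paths(j, j)
    S[i, j] <- if (den > 0) 2 * count_paths(i, j) / den else 0
  }
  S
}

# truncated-series Katz oracle, written independently of katz_kernel
katz_series_oracle <- function(P, mu, terms = 200) {
  n <- nrow(P)
  K <- matrix(0, n, n)
  term <- diag(n)
  for (m in seq_len(terms)) {
    term <- term %*% (mu * P)
    K <- K + term
  }
  K
}

# pairwise (double-loop) supervision term: the literal ordered sum
supervision_pairwise <- function(E, S) {
  total <- 0
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S)))
    total <- total + S[i, j] * sum((E[i, ] - E[j, ])^2)
  total
}

# brute-force ROC-AUC over all positive-negative pairs (ties count half)
roc_auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# AP@K by direct definition (cumulative precision loop over ranks)
ap_at_k_oracle <- function(ranking, relevant, k) {
  L <- length(relevant)
  k <- min(k, length(ranking))
  hits <- 0; acc <- 0
  for (r in seq_len(k)) {
    if (ranking[r] %in% relevant) {
      hits <- hits + 1
      acc <- acc + hits / r
    }
  }
  acc / min(L, k)
}

# random symmetric proximity in [0, 1] with unit diagonal
random_proximity <- function(n, seed = 1, meta_path = "DCD") {
  set.seed(seed)
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  rownames(S) <- colnames(S) <- sprintf("D%02d", 1:n)
  meta_path_proximity(meta_path, S, normalized = TRUE)
}
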