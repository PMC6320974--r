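#' Construct a meta-path proximity matrix
#'
#' A symmetric nonnegative drugs-x-drugs proximity tagged with the meta-path
#' that produced it. Meta-paths: `DD` (interaction-profile Jaccard), `DCD`,
#' `DPD`, `DDID`, `DSED` (PathSim over shared substructures / targets /
#' diseases / side effects) and `DPnD` (target propagation through the PPI
#' network, n >= 2 hops).
#'
#' @param meta_path one of `DD, DCD, DPD, DPnD, DDID, DSED`.
#' @param S symmetric nonnegative numeric matrix (dense), drugs x drugs.
#' @param normalized whether entries are already on the common \[0, 1\] scale.
#' @param validate check invariants (default `TRUE`).
#' @return a `meta_path_proximity` object.
#' @export
meta_path_proximity <- function(meta_path, S, normalized = FALSE,
                                validate = TRUE) {
  meta_path <- match.arg(meta_path, .META_PATHS)
  S <- as.matrix(S)
  obj <- structure(list(meta_path = meta_path, S = S, normalized = normalized),
                   class = "meta_path_proximity")
  if (validate) validate_proximity(obj)
  obj
}

#' Validate a meta-path proximity
#'
#' @param prox a `meta_path_proximity`.
#' @param tol numeric tolerance for the symmetry check.
#' @return invisibly `TRUE`.
#' @export
validate_proximity <- function(prox, tol = 1e-10) {
  S <- prox$S
  if (nrow(S) != ncol(S)) .stopf("proximity matrix must be square")
  if (length(S) && !all(is.finite(S))) .stopf("non-finite proximity entries")
  if (any(S < 0)) .stopf("negative proximity entries")
  if (max(abs(S - t(S))) > tol) .stopf("proximity matrix not symmetric")
  if (prox$normalized && length(S) && max(S) > 1 + tol)
    .stopf("normalized proximity has entries > 1")
  invisible(TRUE)
}

#' @exportS3Method base::print
print.meta_path_proximity <- function(x, ...) {
  cat(sprintf("meta_path_proximity [%s]: %d x %d, %snormalized\n",
              x$meta_path, nrow(x$S), ncol(x$S),
              if (x$normalized) "" else "not "))
  invisible(x)
}

#' Jaccard proximity over drug-drug interaction profiles (meta-path DD)
#'
#' For drugs i and j with binary interaction vectors (rows of `A_dd`),
#' `S[i,j] = |Di & Dj| / |Di | Dj|`; 0 when both vectors are empty.
#' Interaction types are collapsed to occurrence at this stage.
#'
#' @param hin a `drug_hin`.
#' @return a normalized `meta_path_proximity` with `meta_path = "DD"`.
#' @export
jaccard_dd <- function(hin) {
  A <- as.matrix(hin$A_dd)
  inter <- A %*% t(A)
  sz <- rowSums(A)
  uni <- outer(sz, sz, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  dimnames(S) <- list(hin$drugs, hin$drugs)
  meta_path_proximity("DD", S, normalized = TRUE)
}

#' PathSim proximity along a drug-X-drug meta-path
#'
#' With path-instance counts `C = M %*% t(M)`,
#' `S[i,j] = 2 C[i,j] / (C[i,i] + C[j,j])`; 0 when the denominator is 0, so
#' the diagonal is 1 exactly for drugs with at least one neighbor in `M`.
#'
#' @param M binary drugs-x-attribute incidence matrix (`M_dc`, `M_dp`,
#'   `M_dse` or `M_ddi`).
#' @param meta_path tag for the result (`DCD`, `DPD`, `DSED` or `DDID`).
#' @return a normalized `meta_path_proximity`.
#' @export
pathsim <- function(M, meta_path = "DCD") {
  C <- as.matrix(Matrix::tcrossprod(M))
  d <- diag(C)
  den <- outer(d, d, "+")
  S <- ifelse(den > 0, 2 * C / den, 0)
  dimnames(S) <- list(rownames(M), rownames(M))
  meta_path_proximity(meta_path, S, normalized = TRUE)
}

#' Random-walk transition matrix of the PPI network
#'
#' `P[u,v] = A_pp[u,v] / degree(u)` for proteins with at least one PPI edge;
#' isolated proteins get an all-zero row.
#'
#' @param hin a `drug_hin`, or a symmetric binary adjacency matrix.
#' @return a sparse row-stochastic (or zero-row) matrix.
#' @export
ppi_transition <- function(hin) {
  A <- if (inherits(hin, "drug_hin")) hin$A_pp else
    .as_relation(hin, rownames(hin) %||% seq_len(nrow(hin)),
                 colnames(hin) %||% seq_len(ncol(hin)))
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(x = inv) %*% A
}

#' Katz random-walk kernel on the PPI transition matrix
#'
#' The damped-walk kernel `K = sum_{m>=1} (mu P)^m = (I - mu P)^{-1} - I`
#' that scores multi-hop reachability between proteins: at least one PPI hop,
#' with longer walks damped geometrically by `mu`. The `solve` backend
#' computes the closed form by a linear solve; the `series` backend returns
#' the truncated sum (useful as an independent check).
#'
#' @param P row-(sub)stochastic transition matrix from [ppi_transition()].
#' @param mu damping factor in `[0, 1)`; 0.98 by default.
#' @param method `"solve"` (closed form, default) or `"series"`.
#' @param series_terms number of terms for the series backend.
#' @return a `propagation_kernel` object with fields `P, mu, K, method,
#'   series_terms`.
#' @export
katz_kernel <- function(P, mu = 0.98, method = c("solve", "series"),
                        series_terms = 200) {
  method <- match.arg(method)
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0 || mu >= 1)
    .stopf("mu must lie in [0, 1); got %s (the geometric walk series diverges at mu >= 1)",
           format(mu))
  Pd <- as.matrix(P)
  n <- nrow(Pd)
  if (n != ncol(Pd)) .stopf("P must be square")
  if (any(Pd < 0)) .stopf("P has negative entries")
  if (any(Matrix::rowSums(Pd) > 1 + 1e-8)) .stopf("P is not row-substochastic")
  if (mu == 0) {
    K <- matrix(0, n, n, dimnames = dimnames(Pd))
  } else if (method == "solve") {
    K <- solve(diag(n) - mu * Pd) - diag(n)
    dimnames(K) <- dimnames(Pd)
  } else {
    term <- mu * Pd
    K <- term
    for (m in seq_len(series_terms - 1)) {
      term <- term %*% (mu * Pd)
      K <- K + term
    }
  }
  K[K < 0 & K > -1e-12] <- 0   # clip solver round-off
  if (any(K < 0)) .stopf("negative kernel entries; mu too close to 1?")
  structure(list(P = P, mu = mu, K = K, method = method,
                 series_terms = if (method == "series") series_terms else NA_integer_),
            class = "propagation_kernel")
}

#' Target-propagation proximity (meta-path DP(n)D, n >= 2)
#'
#' Scores a drug pair by damped random-walk reachability between their target
#' sets through the PPI network: raw `R = M_dp K t(M_dp)` with the Katz
#' kernel `K`, symmetrized as `(R + t(R)) / 2` (row normalization of `P`
#' makes the raw matrix asymmetric) and min-max scaled to `[0, 1]` so all
#' meta-path proximities share a supervision scale. Drugs without targets
#' have all-zero rows/columns.
#'
#' @param hin a `drug_hin`.
#' @param kernel a `propagation_kernel` over the same protein registry;
#'   computed from `hin` when `NULL`.
#' @param mu,method,series_terms kernel parameters, used when `kernel` is
#'   `NULL`.
#' @param normalize min-max scale to `[0, 1]` (default `TRUE`).
#' @return a `meta_path_proximity` with `meta_path = "DPnD"`; attributes
#'   `raw_min` / `raw_max` record the normalization constants.
#' @export
target_propagation_proximity <- function(hin, kernel = NULL, mu = 0.98,
                                         method = "solve", series_terms = 200,
                                         normalize = TRUE) {
  if (is.null(kernel))
    kernel <- katz_kernel(ppi_transition(hin), mu = mu, method = method,
                          series_terms = series_terms)
  if (nrow(kernel$K) != length(hin$prots))
    .stopf("kernel is over %d proteins; HIN registry has %d",
           nrow(kernel$K), length(hin$prots))
  D <- as.matrix(hin$M_dp)
  R <- D %*% kernel$K %*% t(D)
  S <- (R + t(R)) / 2
  rmin <- if (length(S)) min(S) else 0
  rmax <- if (length(S)) max(S) else 0
  if (normalize) {
    S <- if (rmax > rmin) (S - rmin) / (rmax - rmin) else S * 0
  }
  dimnames(S) <- list(hin$drugs, hin$drugs)
  out <- meta_path_proximity("DPnD", S, normalized = normalize)
  attr(out, "raw_min") <- rmin
  attr(out, "raw_max") <- rmax
  out
}

#' Build all six meta-path sub-networks
#'
#' Computes the full set of meta-path proximities \{DD, DCD, DPD, DPnD,
#' DDID, DSED\}, each symmetric and on the `[0, 1]` scale, which serve as the
#' weighted sub-networks fed to the per-meta-path encoders.
#'
#' @param hin a `drug_hin`.
#' @param mu damping factor of the target-propagation kernel (default 0.98).
#' @param method kernel backend, `"solve"` or `"series"`.
#' @param series_terms series length for the `"series"` backend.
#' @return named list of six `meta_path_proximity` objects.
#' @export
build_subnetworks <- function(hin, mu = 0.98, method = "solve",
                              series_terms = 200) {
  list(
    DD   = jaccard_dd(hin),
    DCD  = pathsim(hin$M_dc, "DCD"),
    DPD  = pathsim(hin$M_dp, "DPD"),
    DPnD = target_propagation_proximity(hin, mu = mu, method = method,
                                        series_terms = series_terms),
    DDID = pathsim(hin$M_ddi, "DDID"),
    DSED = pathsim(hin$M_dse, "DSED")
  )
}
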