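#' Synthetic drug-HIN configuration
#'
#' Defaults are the desk-scale study conditions: 120 drugs in 4 clusters,
#' 150 proteins, 60 substructures, 40 side effects, 30 diseases, with
#' side effects planted 2 PPI hops deep and light observation noise.
#'
#' @param n_drugs,n_chems,n_prots,n_ses,n_dis node counts.
#' @param n_clusters planted drug clusters (each aligned with one PPI
#'   community).
#' @param bit_flip_noise per-bit flip rate applied to the cluster prototype
#'   vectors (substructures, diseases); density-preserving for sparse
#'   vectors: ones flip off at this rate, zeros flip on at a rate scaled so
#'   the expected number of ones is unchanged.
#' @param targets_per_drug number of target proteins per drug, sampled *per
#'   drug* from the cluster's PPI community (plus rare off-community flips at
#'   `bit_flip_noise`), so drugs of one cluster have nearby but individually
#'   distinct target sets - the situation in which multi-hop propagation
#'   carries information that exact target sharing does not.
#' @param ppi_within_p,ppi_between_p stochastic-block-model edge
#'   probabilities of the PPI graph. The within-community default (0.07)
#'   keeps hop-bounded neighborhoods specific subsets of a community rather
#'   than covering it, so side-effect labels vary between drugs of the same
#'   cluster.
#' @param propagation_hops side effects attach to every drug with a target
#'   within this many PPI hops of the side effect's anchor protein.
#' @param se_noise symmetric flip rate of observed side-effect / DDI-type
#'   labels.
#' @param ddi_base_rate interaction probability of cross-cluster drug pairs.
#' @param ddi_within_rate elevated interaction probability within a cluster.
#' @param seed RNG seed; everything is reproducible from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_drugs = 120, n_chems = 60, n_prots = 150,
                         n_ses = 40, n_dis = 30, n_clusters = 4,
                         bit_flip_noise = 0.1, targets_per_drug = 3,
                         ppi_within_p = 0.07, ppi_between_p = 0.01,
                         propagation_hops = 2, se_noise = 0.05,
                         ddi_base_rate = 0.05, ddi_within_rate = 0.35,
                         seed = 1L) {
  cfg <- list(n_drugs = n_drugs, n_chems = n_chems, n_prots = n_prots,
              n_ses = n_ses, n_dis = n_dis, n_clusters = n_clusters,
              bit_flip_noise = bit_flip_noise,
              targets_per_drug = targets_per_drug,
              ppi_within_p = ppi_within_p, ppi_between_p = ppi_between_p,
              propagation_hops = as.integer(propagation_hops),
              se_noise = se_noise, ddi_base_rate = ddi_base_rate,
              ddi_within_rate = ddi_within_rate, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_drugs > 0, n_chems > 0, n_prots > 0, n_ses > 0, n_dis > 0,
              n_clusters >= 1, n_clusters <= n_drugs,
              bit_flip_noise >= 0, bit_flip_noise <= 1,
              targets_per_drug >= 1,
              ppi_within_p >= 0, ppi_within_p <= 1,
              ppi_between_p >= 0, ppi_between_p <= 1,
              propagation_hops >= 1, se_noise >= 0, se_noise <= 1,
              ddi_base_rate >= 0, ddi_base_rate <= 1,
              ddi_within_rate >= 0, ddi_within_rate <= 1)
  })
  if (cfg$targets_per_drug > cfg$n_prots %/% cfg$n_clusters)
    .stopf("targets_per_drug (%d) exceeds the per-community protein budget (%d)",
           cfg$targets_per_drug, cfg$n_prots %/% cfg$n_clusters)
  structure(cfg, class = "synth_config")
}

# density-preserving bit flips: 1 -> 0 w.p. p, 0 -> 1 w.p. p * k1 / k0
.flip_bits <- function(v, p) {
  if (p == 0) return(v)
  k1 <- sum(v)
  k0 <- length(v) - k1
  p01 <- if (k0 > 0) min(1, p * k1 / k0) else 0
  flips <- ifelse(v == 1, stats::runif(length(v)) < p,
                  stats::runif(length(v)) < p01)
  as.numeric(xor(v == 1, flips))
}

# hop-bounded reachability (incl. distance 0) by repeated sparse products:
# the exactly computable ground truth for what the propagation kernel scores
.hop_reach <- function(A, hops) {
  n <- nrow(A)
  R <- Matrix::Diagonal(n) + A
  acc <- R
  if (hops >= 2) for (h in 2:hops) acc <- (acc %*% R) != 0
  as(acc != 0, "CsparseMatrix") * 1
}

#' Generate a synthetic drug HIN with known structure
#'
#' Drugs are partitioned into clusters; each cluster has prototype
#' substructure, target and disease vectors and per-drug vectors are noisy
#' copies. The PPI graph is a stochastic block model whose communities align
#' with the cluster target sets. Each side effect is anchored at a protein:
#' a drug carries it (noise-free) iff some target lies within
#' `propagation_hops` PPI hops of the anchor, which is exactly the multi-hop
#' signal the target-propagation meta-path is designed to capture. DDIs are
#' denser within clusters; DDI event types reuse the side-effect mechanism on
#' the union of the pair's targets.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `hin` (a `drug_hin`), `truth` (a `synth_truth`:
#'   `cluster_of`, `se_anchor`, `planted` noise-free label matrices) and
#'   `tasks` (the three [task_dataset()] objects).
#' @export
generate_hin <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  drugs <- sprintf("D%03d", seq_len(cfg$n_drugs))
  chems <- sprintf("C%03d", seq_len(cfg$n_chems))
  prots <- sprintf("P%03d", seq_len(cfg$n_prots))
  ses   <- sprintf("SE%03d", seq_len(cfg$n_ses))
  dis   <- sprintf("DI%03d", seq_len(cfg$n_dis))
  k <- cfg$n_clusters

  cluster_of <- sort(rep(seq_len(k), length.out = cfg$n_drugs))
  prot_comm <- sort(rep(seq_len(k), length.out = cfg$n_prots))

  proto_chem <- matrix(stats::rbinom(k * cfg$n_chems, 1, 0.15), k)
  proto_dis  <- matrix(stats::rbinom(k * cfg$n_dis, 1, 0.15), k)

  draw <- function(proto) {
    t(vapply(seq_len(cfg$n_drugs),
             function(i) .flip_bits(proto[cluster_of[i], ], cfg$bit_flip_noise),
             numeric(ncol(proto))))
  }
  M_dc <- draw(proto_chem)
  M_ddi <- draw(proto_dis)
  # targets: sampled per drug from the cluster's protein community, then
  # noisy bit flips - nearby but individually distinct target sets
  M_dp <- matrix(0, cfg$n_drugs, cfg$n_prots)
  for (i in seq_len(cfg$n_drugs)) {
    own <- sample(which(prot_comm == cluster_of[i]), cfg$targets_per_drug)
    v <- numeric(cfg$n_prots); v[own] <- 1
    M_dp[i, ] <- .flip_bits(v, cfg$bit_flip_noise)
  }

  # PPI: stochastic block model aligned with the protein communities
  A_pp <- matrix(0, cfg$n_prots, cfg$n_prots)
  ut <- which(upper.tri(A_pp), arr.ind = TRUE)
  p_edge <- ifelse(prot_comm[ut[, 1]] == prot_comm[ut[, 2]],
                   cfg$ppi_within_p, cfg$ppi_between_p)
  edge <- stats::rbinom(nrow(ut), 1, p_edge)
  A_pp[ut] <- edge
  A_pp <- A_pp + t(A_pp)

  # side effects planted via hop-bounded PPI reachability from anchor proteins
  se_anchor <- sample(cfg$n_prots, cfg$n_ses, replace = cfg$n_ses > cfg$n_prots)
  reach <- as.matrix(.hop_reach(Matrix::Matrix(A_pp, sparse = TRUE),
                                cfg$propagation_hops))
  planted_dse <- (M_dp %*% reach[, se_anchor, drop = FALSE] > 0) * 1
  flip_se <- matrix(stats::runif(length(planted_dse)) < cfg$se_noise,
                    nrow(planted_dse))
  M_dse <- (xor(planted_dse == 1, flip_se)) * 1

  # DDI occurrence: elevated within clusters
  A_dd <- matrix(0, cfg$n_drugs, cfg$n_drugs)
  utd <- which(upper.tri(A_dd), arr.ind = TRUE)
  p_dd <- ifelse(cluster_of[utd[, 1]] == cluster_of[utd[, 2]],
                 cfg$ddi_within_rate, cfg$ddi_base_rate)
  A_dd[utd] <- stats::rbinom(nrow(utd), 1, p_dd)
  A_dd <- A_dd + t(A_dd)

  # DDI types for interacting pairs: union-of-targets reachability to anchors
  pos <- utd[A_dd[utd] == 1, , drop = FALSE]
  pair_reach <- (M_dp[pos[, 1], , drop = FALSE] +
                   M_dp[pos[, 2], , drop = FALSE] > 0) * 1
  planted_types <- (pair_reach %*% reach[, se_anchor, drop = FALSE] > 0) * 1
  flip_t <- matrix(stats::runif(length(planted_types)) < cfg$se_noise,
                   nrow(planted_types))
  type_lab <- (xor(planted_types == 1, flip_t)) * 1
  colnames(type_lab) <- ses
  pair_inst <- cbind(drugs[pos[, 1]], drugs[pos[, 2]])

  hin <- drug_hin(drugs, chems, prots, ses, dis,
                  A_dd, M_dc, M_dp, M_dse, M_ddi, A_pp)
  truth <- structure(
    list(cluster_of = stats::setNames(cluster_of, drugs),
         se_anchor = stats::setNames(prots[se_anchor], ses),
         planted = list(M_dse = `dimnames<-`(planted_dse, list(drugs, ses)),
                        ddi_types = `dimnames<-`(planted_types,
                                                 list(NULL, ses)),
                        ddi_pairs = pair_inst)),
    class = "synth_truth")

  dse_lab <- M_dse; dimnames(dse_lab) <- list(drugs, ses)
  all_pairs <- cbind(drugs[utd[, 1]], drugs[utd[, 2]])
  tasks <- list(
    single_drug_se = task_dataset("single_drug_se", drugs, dse_lab),
    ddi_occurrence = task_dataset("ddi_occurrence", all_pairs,
                                  A_dd[utd]),
    ddi_type = task_dataset("ddi_type", pair_inst, type_lab)
  )
  list(hin = hin, truth = truth, tasks = tasks, config = cfg)
}

#' Small fixed synthetic instance
#'
#' A 12-drug, 3-cluster, 20-protein HIN regenerated bit-identically from a
#' fixed seed; small enough that its proximities can be checked by hand or
#' against enumeration oracles.
#'
#' @return list with `hin` and `truth` (see [generate_hin()]).
#' @export
fixture_small <- function() {
  cfg <- synth_config(n_drugs = 12, n_chems = 15, n_prots = 20, n_ses = 8,
                      n_dis = 6, n_clusters = 3, bit_flip_noise = 0.05,
                      targets_per_drug = 2, ppi_within_p = 0.4,
                      ppi_between_p = 0.05, propagation_hops = 2,
                      se_noise = 0.02, ddi_base_rate = 0.1,
                      ddi_within_rate = 0.5, seed = 4242L)
  g <- generate_hin(cfg)
  list(hin = g$hin, truth = g$truth, tasks = g$tasks, config = cfg)
}
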