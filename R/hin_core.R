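#' @import Matrix
#' @importFrom methods as is
NULL

# relation slot -> (row registry, col registry, symmetric?)
.REL_SCHEMA <- list(
  A_dd  = c("drugs", "drugs", TRUE),
  M_dc  = c("drugs", "chems", FALSE),
  M_dp  = c("drugs", "prots", FALSE),
  M_dse = c("drugs", "ses",   FALSE),
  M_ddi = c("drugs", "dis",   FALSE),
  A_pp  = c("prots", "prots", TRUE)
)

# file-name stems used on disk for each relation
.REL_FILES <- c(A_dd = "dd", M_dc = "dc", M_dp = "dp", M_dse = "dse",
                M_ddi = "ddi", A_pp = "pp")

.META_PATHS <- c("DD", "DCD", "DPD", "DPnD", "DDID", "DSED")

.as_relation <- function(m, rows, cols) {
  m <- as(as(Matrix::Matrix(m, sparse = TRUE), "dMatrix"), "CsparseMatrix")
  m <- as(m, "generalMatrix")
  dimnames(m) <- list(as.character(rows), as.character(cols))
  m
}

#' Construct a drug heterogeneous information network
#'
#' The container holds the five node registries (drugs, chemical
#' substructures, target proteins, side effects, diseases) and the six binary
#' relation matrices of the drug HIN: drug-drug interaction occurrence
#' (`A_dd`, type-collapsed), drug-substructure (`M_dc`), drug-target
#' (`M_dp`), drug-side-effect (`M_dse`), drug-disease (`M_ddi`) and
#' protein-protein interactions (`A_pp`). The protein registry is shared by
#' `M_dp` and `A_pp`: drug targets live inside the PPI universe, and proteins
#' without any PPI edge are kept as isolated nodes.
#'
#' @param drugs,chems,prots,ses,dis character vectors of node IDs (unique
#'   within each registry); their order fixes matrix row/column order.
#' @param A_dd,M_dc,M_dp,M_dse,M_ddi,A_pp binary relation matrices (dense or
#'   sparse); `A_dd` and `A_pp` must be symmetric with zero diagonal.
#' @param validate run [validate_hin()] on the result (default `TRUE`).
#' @return an object of class `drug_hin`.
#' @export
drug_hin <- function(drugs, chems, prots, ses, dis,
                     A_dd, M_dc, M_dp, M_dse, M_ddi, A_pp,
                     validate = TRUE) {
  hin <- structure(
    list(drugs = as.character(drugs), chems = as.character(chems),
         prots = as.character(prots), ses = as.character(ses),
         dis = as.character(dis),
         A_dd  = .as_relation(A_dd, drugs, drugs),
         M_dc  = .as_relation(M_dc, drugs, chems),
         M_dp  = .as_relation(M_dp, drugs, prots),
         M_dse = .as_relation(M_dse, drugs, ses),
         M_ddi = .as_relation(M_ddi, drugs, dis),
         A_pp  = .as_relation(A_pp, prots, prots)),
    class = "drug_hin")
  if (validate) validate_hin(hin)
  hin
}

#' Validate a drug HIN against its structural invariants
#'
#' Checks ID uniqueness, dimension consistency between matrices and
#' registries, binary entries everywhere, and symmetry plus zero diagonal of
#' the two homogeneous adjacency matrices.
#'
#' @param hin a `drug_hin`.
#' @return invisibly `TRUE`; errors on the first violated invariant.
#' @export
validate_hin <- function(hin) {
  if (!inherits(hin, "drug_hin")) .stopf("not a drug_hin object")
  regs <- c("drugs", "chems", "prots", "ses", "dis")
  for (r in regs) {
    ids <- hin[[r]]
    if (anyDuplicated(ids)) .stopf("duplicate IDs in registry '%s'", r)
  }
  for (slot in names(.REL_SCHEMA)) {
    sch <- .REL_SCHEMA[[slot]]
    m <- hin[[slot]]
    nr <- length(hin[[sch[1]]]); nc <- length(hin[[sch[2]]])
    if (nrow(m) != nr || ncol(m) != nc)
      .stopf("%s has dim %d x %d, expected %d x %d (registries %s x %s)",
             slot, nrow(m), ncol(m), nr, nc, sch[1], sch[2])
    if (!.is_binary(m)) .stopf("%s has non-binary entries", slot)
    if (as.logical(sch[3])) {
      if (!.is_symmetric_sparse(m)) .stopf("%s is not symmetric", slot)
      if (any(Matrix::diag(m) != 0)) .stopf("%s has nonzero diagonal", slot)
    }
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.drug_hin <- function(x, ...) {
  cat(sprintf(
    "drug_hin: %d drugs, %d substructures, %d proteins, %d side effects, %d diseases\n",
    length(x$drugs), length(x$chems), length(x$prots), length(x$ses),
    length(x$dis)))
  cat(sprintf("  edges: DD=%d DC=%d DP=%d DSE=%d DDI=%d PP=%d\n",
              Matrix::nnzero(x$A_dd) / 2, Matrix::nnzero(x$M_dc),
              Matrix::nnzero(x$M_dp), Matrix::nnzero(x$M_dse),
              Matrix::nnzero(x$M_ddi), Matrix::nnzero(x$A_pp) / 2))
  invisible(x)
}

.read_node_list <- function(path) {
  if (!file.exists(path)) .stopf("node list not found: %s", path)
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) .stopf("duplicate node IDs in %s", path)
  x
}

.read_edge_tsv <- function(path) {
  if (!file.exists(path)) .stopf("edge file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(matrix(character(), ncol = 2))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) .stopf("malformed edge line %d in %s", bad[1], path)
  cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

.read_relation <- function(path, rows, cols, symmetric, symmetrize = FALSE) {
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    if (nrow(m) != length(rows) || ncol(m) != length(cols))
      .stopf("%s: matrix dim %d x %d does not match registries %d x %d",
             path, nrow(m), ncol(m), length(rows), length(cols))
    m <- .as_relation(m != 0, rows, cols)
    if (symmetric) {
      if (!.is_symmetric_sparse(m)) {
        if (!symmetrize) .stopf("%s: asymmetric input for a symmetric relation", path)
        m <- .as_relation((m + Matrix::t(m)) != 0, rows, cols)
      }
      Matrix::diag(m) <- 0
      m <- Matrix::drop0(m)
    }
    return(m)
  }
  edges <- .read_edge_tsv(path)
  ri <- match(edges[, 1], rows)
  ci <- match(edges[, 2], cols)
  if (anyNA(ri)) .stopf("%s: unregistered source ID '%s'", path,
                        edges[which(is.na(ri))[1], 1])
  if (anyNA(ci)) .stopf("%s: unregistered target ID '%s'", path,
                        edges[which(is.na(ci))[1], 2])
  if (symmetric) {
    # an undirected edge list: each line contributes both (i,j) and (j,i)
    keep <- ri != ci
    ri0 <- ri[keep]; ci0 <- ci[keep]
    ri <- c(ri0, ci0); ci <- c(ci0, ri0)
  }
  m <- Matrix::sparseMatrix(i = ri, j = ci, x = 1,
                            dims = c(length(rows), length(cols)))
  m <- .as_relation(m != 0, rows, cols)   # duplicates collapse to 1
  m
}

#' Read a drug HIN from a config of node lists and relation files
#'
#' The config (YAML path or list) names five node-registry files (one ID per
#' line, `#` comments allowed) under `nodes:` and six relation files under
#' `relations:` with keys `dd, dc, dp, dse, ddi, pp`. Each relation file is
#' either a two-column tab-separated edge list or a MatrixMarket `.mtx`
#' coordinate file (dimensions must match the registries). Relative paths
#' are resolved against the config file's directory.
#'
#' For the symmetric relations (`dd`, `pp`) an edge-list line is treated as
#' an undirected edge; a MatrixMarket matrix must be symmetric unless
#' `symmetrize = TRUE`, in which case it is OR-symmetrized. Duplicate edges
#' collapse to a single 1; self-loops in symmetric relations are dropped.
#'
#' @param config path to a YAML file, or an equivalent named list (with
#'   optional `base_dir` for resolving relative paths).
#' @param symmetrize permit OR-symmetrization of asymmetric matrix input for
#'   `dd` / `pp` instead of erroring.
#' @return a validated [drug_hin()].
#' @export
read_hin <- function(config, symmetrize = FALSE) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config, mustWork = TRUE))
    cfg <- yaml::read_yaml(config)
  } else {
    cfg <- config
    base <- cfg$base_dir %||% "."
  }
  need <- c("drugs", "chems", "prots", "ses", "dis")
  if (!all(need %in% names(cfg$nodes)))
    .stopf("config$nodes must name files for: %s", paste(need, collapse = ", "))
  if (!all(.REL_FILES %in% names(cfg$relations)))
    .stopf("config$relations must name files for: %s",
           paste(.REL_FILES, collapse = ", "))
  p <- function(f) if (grepl("^/", f)) f else file.path(base, f)
  nodes <- lapply(cfg$nodes[need], function(f) .read_node_list(p(f)))
  rel <- list()
  for (slot in names(.REL_SCHEMA)) {
    sch <- .REL_SCHEMA[[slot]]
    rel[[slot]] <- .read_relation(p(cfg$relations[[.REL_FILES[[slot]]]]),
                                  nodes[[sch[1]]], nodes[[sch[2]]],
                                  symmetric = as.logical(sch[3]),
                                  symmetrize = symmetrize)
  }
  drug_hin(nodes$drugs, nodes$chems, nodes$prots, nodes$ses, nodes$dis,
           rel$A_dd, rel$M_dc, rel$M_dp, rel$M_dse, rel$M_ddi, rel$A_pp)
}

.write_edge_tsv <- function(m, path, symmetric) {
  tri <- Matrix::summary(as(m, "TsparseMatrix"))
  idx <- cbind(tri$i, tri$j)
  if (symmetric && nrow(idx)) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  rn <- rownames(m); cn <- colnames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# source_id\ttarget_id", con)
  if (nrow(idx)) {
    o <- order(idx[, 1], idx[, 2])
    idx <- idx[o, , drop = FALSE]
    writeLines(paste(rn[idx[, 1]], cn[idx[, 2]], sep = "\t"), con)
  }
  invisible(path)
}

#' Write a drug HIN to a directory
#'
#' Writes the five node registries and six relation files plus a
#' `config.yaml` that [read_hin()] consumes; `read_hin(write_hin(hin))`
#' round-trips exactly.
#'
#' @param hin a `drug_hin`.
#' @param dir output directory (created if missing).
#' @param format `"edgelist"` (TSV, default) or `"matrixmarket"`.
#' @return path to the written `config.yaml`, invisibly.
#' @export
write_hin <- function(hin, dir, format = c("edgelist", "matrixmarket")) {
  format <- match.arg(format)
  validate_hin(hin)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regs <- c(drugs = "drugs.txt", chems = "chems.txt", prots = "prots.txt",
            ses = "ses.txt", dis = "dis.txt")
  for (r in names(regs)) writeLines(hin[[r]], file.path(dir, regs[[r]]))
  ext <- if (format == "edgelist") ".tsv" else ".mtx"
  relfiles <- stats::setNames(paste0(.REL_FILES, ext), names(.REL_FILES))
  for (slot in names(.REL_SCHEMA)) {
    f <- file.path(dir, relfiles[[slot]])
    if (format == "edgelist") {
      .write_edge_tsv(hin[[slot]], f, symmetric = as.logical(.REL_SCHEMA[[slot]][3]))
    } else {
      Matrix::writeMM(hin[[slot]], f)
    }
  }
  cfg <- list(nodes = as.list(regs),
              relations = stats::setNames(as.list(unname(relfiles)),
                                          unname(.REL_FILES)))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

#' Construct an embedding matrix
#'
#' @param ids character drug IDs, in the same order as the HIN drug registry.
#' @param E numeric matrix, one row per drug, `d` columns.
#' @param source tag: a meta-path identifier, `"concat"` or `"final"`.
#' @return an `embedding_matrix` object.
#' @export
embedding_matrix <- function(ids, E, source = "final") {
  E <- as.matrix(E)
  if (nrow(E) != length(ids)) .stopf("embedding rows (%d) != ids (%d)",
                                     nrow(E), length(ids))
  if (length(E) && !all(is.finite(E))) .stopf("non-finite embedding entries")
  rownames(E) <- ids
  colnames(E) <- paste0("dim_", seq_len(ncol(E)) - 1L)
  structure(list(ids = as.character(ids), E = E, source = source),
            class = "embedding_matrix")
}

#' @exportS3Method base::print
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("embedding_matrix [%s]: %d drugs x %d dims\n",
              x$source, nrow(x$E), ncol(x$E)))
  invisible(x)
}

#' Write embeddings as TSV
#'
#' Header row `id, dim_0, ..., dim_{d-1}`; 17 significant digits so a
#' read-back reproduces the matrix to float round-trip tolerance.
#'
#' @param emb an [embedding_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  d <- ncol(emb$E)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", paste0("dim_", seq_len(d) - 1L)), collapse = "\t"), con)
  if (nrow(emb$E)) {
    body <- apply(format(emb$E, digits = 17, scientific = TRUE, trim = TRUE),
                  1, paste, collapse = "\t")
    writeLines(paste(emb$ids, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#'
#' @param path TSV file with header `id, dim_0, ...`.
#' @param source source tag to attach (not stored in the file).
#' @return an [embedding_matrix()].
#' @export
read_embeddings <- function(path, source = "file") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = NA, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "id") .stopf("%s: first column must be 'id'", path)
  E <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(E) <- "double"
  embedding_matrix(as.character(df$id), E, source = source)
}
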