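`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage / per-repetition
#' seeds so every stochastic component of a pipeline run is independently
#' reproducible. Kept below 2^31 - 1 so the result is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param ... integer offsets identifying the stage/repetition.
#' @return an integer seed.
#' @export
derive_seed <- function(master, ...) {
  offs <- c(...)
  x <- as.double(master) %% 2147483647
  for (o in offs) {
    x <- (x * 7919 + as.double(o) + 1) %% 2147483647
  }
  as.integer(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_binary <- function(m) {
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  length(x) == 0 || all(x %in% c(0, 1))
}

.is_symmetric_sparse <- function(m) {
  isTRUE(all.equal(as(m, "generalMatrix"), as(Matrix::t(m), "generalMatrix"),
                   tolerance = 0, check.attributes = FALSE))
}

# canonical unordered-pair key
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "||")
}

split_pair_key <- function(keys) {
  parts <- strsplit(keys, "||", fixed = TRUE)
  cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' All unordered drug pairs
#'
#' @param drugs character vector of drug IDs.
#' @return character matrix with two columns, one row per unordered pair.
#' @export
all_drug_pairs <- function(drugs) {
  if (length(drugs) < 2) return(matrix(character(), ncol = 2))
  t(utils::combn(drugs, 2))
}
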