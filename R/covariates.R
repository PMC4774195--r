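#' Read a PHYLIP square distance matrix
#'
#' Reads the square-matrix output of PROTDIST (and kin): a first line with
#' the taxon count, then one row per taxon starting with its name followed
#' by the distances, possibly wrapped across several lines.  Names are
#' whitespace-delimited (long names tolerated).  The matrix is symmetrized
#' by averaging with its transpose.
#'
#' @param path Path to the distance-matrix file.
#' @return A labelled symmetric numeric matrix.
#' @export
read_phylip_square <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE)
  if (!length(tokens)) abort("empty PHYLIP file")
  n <- suppressWarnings(as.integer(tokens[[1]]))
  if (is.na(n) || n < 1) abort("first PHYLIP token must be the taxon count")
  tokens <- tokens[-1]
  if (length(tokens) != n * (n + 1)) {
    abort(sprintf("non-square payload: expected %d tokens for %d taxa, found %d",
                  n * (n + 1), n, length(tokens)))
  }
  labels <- character(n)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    row <- tokens[((i - 1) * (n + 1) + 1):(i * (n + 1))]
    labels[i] <- row[[1]]
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals)) {
      abort(sprintf("non-numeric distance in row for taxon '%s'", labels[i]))
    }
    M[i, ] <- vals
  }
  if (anyDuplicated(labels)) abort("duplicate taxon names")
  M <- (M + t(M)) / 2
  dimnames(M) <- list(labels, labels)
  M
}

#' Write a PHYLIP square distance matrix
#'
#' Inverse of [read_phylip_square()]; values printed with 6 significant
#' digits, one taxon per line (no wrapping).
#'
#' @param mat Labelled square numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_square <- function(mat, path) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            !is.null(rownames(mat)))
  lines <- c(sprintf("%5d", nrow(mat)),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(c(format(rownames(mat)[i], width = 10),
                       formatC(mat[i, ], format = "g", digits = 6)),
                     collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Align sequence-distance covariates to a protein roster
#'
#' Subsets and reorders one or more symmetric distance matrices (e.g. the
#' PAM distances between dimerisation domains DIII, DIV or concatenated
#' DIII/IV) so their rows and columns follow the roster order.  Proteins
#' lacking the domain must already have been excluded upstream.
#'
#' @param matrices Named list of labelled symmetric matrices (or a single
#'   matrix).
#' @param roster Character vector of protein ids, or a roster tibble with a
#'   `protein` column.
#' @return An object of class `covariate_set`: list with `names` and
#'   `matrices` (each N x N, zero diagonal, roster order).
#' @export
align_covariates <- function(matrices, roster) {
  if (is.matrix(matrices)) matrices <- list(Y = matrices)
  if (is.data.frame(roster)) roster <- roster$protein
  if (is.null(names(matrices))) {
    names(matrices) <- paste0("Y", seq_along(matrices))
  }
  out <- purrr::imap(matrices, function(M, nm) {
    missing_ids <- setdiff(roster, rownames(M))
    if (length(missing_ids)) {
      abort(paste0("covariate '", nm, "' is missing protein(s): ",
                   paste(missing_ids, collapse = ", ")))
    }
    A <- M[roster, roster, drop = FALSE]
    A <- (A + t(A)) / 2
    diag(A) <- 0
    if (any(A < 0)) abort(paste0("covariate '", nm, "' has negative distances"))
    A
  })
  structure(list(names = names(out), matrices = out), class = "covariate_set")
}

#' @export
print.covariate_set <- function(x, ...) {
  cat("Covariate set: ", length(x$matrices), " matrix(ces) over ",
      nrow(x$matrices[[1]]), " proteins: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a covariate matrix as labelled TSV
#'
#' @param covariates A `covariate_set`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_covariates <- function(covariates, dir) {
  stopifnot(inherits(covariates, "covariate_set"))
  paths <- purrr::imap_chr(covariates$matrices, function(M, nm) {
    p <- file.path(dir, paste0("covariate-", gsub("[^A-Za-z0-9]+", "_", nm),
                               ".tsv"))
    readr::write_tsv(dplyr::bind_cols(tibble(protein = rownames(M)),
                                      as_tibble(M)), p, progress = FALSE)
    p
  })
  invisible(paths)
}
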