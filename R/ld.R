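#' Construct an LD correlation matrix
#'
#' Validates and lightly repairs a matrix of pairwise genotype correlations
#' (r, not r-squared). Asymmetric input is symmetrised as `(R + t(R))/2`,
#' with a warning when the asymmetry exceeds `1e-8`; negative eigenvalues
#' are clipped to zero and the diagonal restored to 1 so downstream solvers
#' always see a positive semi-definite correlation matrix.
#'
#' @param r Square numeric matrix of correlations.
#' @param ids Variant ids for rows/columns; defaults to existing dimnames.
#' @return The repaired correlation matrix with `ids` as dimnames.
#' @export
ld_matrix <- function(r, ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(r)))
  if (length(ids) != nrow(r)) stop("ids length must match matrix dimension", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("correlations must satisfy |r| <= 1", call. = FALSE)
  }
  asym <- max(abs(r - t(r)))
  if (asym > 1e-8) {
    warning(sprintf("asymmetric LD matrix (max |r - t(r)| = %.3g); symmetrised", asym))
  }
  r <- (r + t(r)) / 2
  r <- make_psd(r)
  dimnames(r) <- list(ids, ids)
  r
}

# Eigenvalue clipping: negative eigenvalues -> 0, then renormalise to unit
# diagonal. A no-op (up to symmetrisation) for matrices already PSD.
make_psd <- function(r, warn = TRUE) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= -1e-12) {
    diag(r) <- 1
    return(r)
  }
  if (warn) {
    warning(sprintf("LD matrix not positive semi-definite (min eigenvalue %.3g); repaired by eigenvalue clipping",
                    min(e$values)))
  }
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Read / write an LD matrix as tab-delimited text
#'
#' The text format is a square block whose first row and first column carry
#' the variant ids. Values round-trip to 12 significant digits. On read the
#' matrix passes through [ld_matrix()], so single-sided entries are
#' symmetrised and non-PSD input repaired with a warning.
#'
#' @param path File path.
#' @param ld For `write_ld`, a matrix as returned by [ld_matrix()].
#' @return `read_ld` returns the LD correlation matrix; `write_ld` returns
#'   `path` invisibly.
#' @export
read_ld <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, na.strings = c(".", "NA"))
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stop("LD matrix file is not square", call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("LD matrix row/column ids do not match", call. = FALSE)
  }
  storage.mode(m) <- "double"
  # entries stored once (upper or lower triangle) appear as NA on the other
  # side; mirror them before validation
  na <- is.na(m)
  if (any(na)) m[na] <- t(m)[na]
  ld_matrix(m)
}

#' @rdname read_ld
#' @export
write_ld <- function(ld, path) {
  stopifnot(is.matrix(ld), nrow(ld) == ncol(ld))
  df <- as.data.frame(signif(ld, 12))
  out <- cbind(ID = rownames(ld), df)
  readr::write_tsv(tibble::as_tibble(out), path)
  invisible(path)
}
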