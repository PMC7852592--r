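# Relationship matrices: pedigree numerator matrix A (with inbreeding), its
# sparse inverse by Henderson's rules with Meuwissen-Luo inbreeding
# coefficients, the VanRaden method-1 genomic matrix G, the Christensen
# moment rescaling of G to the A11 scale, the blended Gw, and the
# single-step H matrix (dense block form and sparse inverse form).

#' Inbreeding coefficients from a pedigree
#'
#' Meuwissen & Luo (1992) algorithm; pedigree rows must be sorted
#' parents-before-offspring.
#'
#' @param ped a [Pedigree]
#' @return numeric vector of inbreeding coefficients, named by id
#' @export
pedigreeInbreeding <- function(ped) {
  f <- ped@frame
  res <- cpp_ainverse(.parentIndex(f, "sire"), .parentIndex(f, "dam"),
                      inverse = FALSE)
  setNames(res$F, as.character(f$id))
}

# parent column as row index into the pedigree frame (0 = unknown)
.parentIndex <- function(f, col) {
  idx <- match(f[[col]], f$id)
  idx[f[[col]] == 0L] <- 0L
  if (anyNA(idx)) stop("parent ids missing from the pedigree")
  as.integer(idx)
}

#' Dense numerator relationship matrix A
#'
#' Tabular (Henderson) recursion with inbreeding. Intended for moderate
#' pedigrees; large evaluations use [buildAinverse()] and never materialise
#' A.
#'
#' @param ped a [Pedigree]
#' @return a [RelationshipMatrix] of kind `"A"`
#' @export
buildA <- function(ped) {
  f <- ped@frame
  n <- nrow(f)
  s <- .parentIndex(f, "sire")
  d <- .parentIndex(f, "dam")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (si > 0L) A[j, si] else 0) +
                    (if (di > 0L) A[j, di] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  dimnames(A) <- list(f$id, f$id)
  new("RelationshipMatrix", values = A, ids = f$id, kind = "A")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding (Mendelian sampling variances from the
#' Meuwissen-Luo coefficients); the inverse is built directly without ever
#' forming A, which keeps single-step evaluations tractable for tens of
#' thousands of animals.
#'
#' @param ped a [Pedigree]
#' @return a [RelationshipMatrix] of kind `"Ainv"` (sparse, `inverse = TRUE`)
#' @export
buildAinverse <- function(ped) {
  f <- ped@frame
  res <- cpp_ainverse(.parentIndex(f, "sire"), .parentIndex(f, "dam"))
  M <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                            dims = c(nrow(f), nrow(f)))
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
  new("RelationshipMatrix", values = M, ids = f$id, kind = "Ainv",
      inverse = TRUE)
}

#' Blocks of A for subsets of animals
#'
#' `A[rows, cols]` computed without forming the full matrix: columns of A
#' are obtained by solving with the sparse inverse (Colleau's indirect
#' method). For small pedigrees the dense recursion is used directly.
#'
#' @param ped a [Pedigree]
#' @param rows,cols individual ids
#' @param ainv optional precomputed [buildAinverse()] result
#' @return dense matrix of relationships
#' @export
relationshipBlock <- function(ped, rows, cols = rows, ainv = NULL) {
  f <- ped@frame
  if (nrow(f) <= 2000 && is.null(ainv)) {
    A <- buildA(ped)@values
    return(A[as.character(rows), as.character(cols), drop = FALSE])
  }
  if (is.null(ainv)) ainv <- buildAinverse(ped)
  ci <- match(cols, f$id)
  if (anyNA(ci) || anyNA(match(rows, f$id))) stop("ids missing from pedigree")
  ch <- Matrix::Cholesky(ainv@values, LDL = FALSE)
  out <- matrix(0, length(rows), length(cols))
  ri <- match(rows, f$id)
  chunk <- 500L
  for (s in seq(1L, length(ci), by = chunk)) {
    e <- min(s + chunk - 1L, length(ci))
    E <- Matrix::sparseMatrix(i = ci[s:e], j = seq_len(e - s + 1L), x = 1,
                              dims = c(nrow(f), e - s + 1L))
    out[, s:e] <- as.matrix(Matrix::solve(ch, E))[ri, , drop = FALSE]
  }
  dimnames(out) <- list(rows, cols)
  out
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = ZZ' / (2 * sum(p_j (1 - p_j)))` with dosages centred by twice the
#' allele frequency. Frequencies are computed from the genotyped animals
#' themselves unless supplied.
#'
#' @param dosages integer matrix of 0/1/2 dosages, individuals x markers,
#'   rownames = ids
#' @param freq optional allele frequencies per marker
#' @return a [RelationshipMatrix] of kind `"G_raw"`
#' @export
buildG <- function(dosages, freq = NULL) {
  if (any(is.na(dosages))) stop("missing genotypes are not supported")
  if (!all(dosages %in% 0:2)) stop("dosages must be coded 0/1/2")
  if (is.null(freq)) freq <- colMeans(dosages) / 2
  poly <- freq > 0 & freq < 1
  if (!any(poly)) stop("all markers are monomorphic")
  Z <- sweep(dosages[, poly, drop = FALSE], 2, 2 * freq[poly])
  denom <- 2 * sum(freq[poly] * (1 - freq[poly]))
  G <- tcrossprod(Z) / denom
  ids <- as.integer(rownames(dosages))
  dimnames(G) <- list(ids, ids)
  new("RelationshipMatrix", values = G, ids = ids, kind = "G_raw",
      genotyped = ids)
}

#' Rescale G to the scale of A11
#'
#' Moment matching: scalars `alpha`, `beta` are chosen so that
#' `beta * G + alpha` has the same mean diagonal and the same overall mean
#' as the pedigree relationships among the genotyped animals (A11).
#'
#' @param G a [RelationshipMatrix] (kind `"G_raw"`)
#' @param A11 dense pedigree relationships among the same animals, same
#'   order
#' @return a [RelationshipMatrix] of kind `"G_adjusted"`
#' @export
rescaleG <- function(G, A11) {
  A11 <- as.matrix(A11)
  gm <- G@values
  if (!all(dim(A11) == dim(gm))) stop("G and A11 dimensions differ")
  md <- c(mean(diag(gm)), mean(gm))
  if (abs(md[1] - md[2]) < 1e-12)
    stop("degenerate G: mean diagonal equals overall mean")
  # solve: beta * mean(diag G) + alpha = mean(diag A11)
  #        beta * mean(G)      + alpha = mean(A11)
  beta <- (mean(diag(A11)) - mean(A11)) / (md[1] - md[2])
  alpha <- mean(diag(A11)) - beta * md[1]
  new("RelationshipMatrix", values = beta * gm + alpha, ids = G@ids,
      kind = "G_adjusted", genotyped = G@genotyped)
}

#' Blend the genomic matrix with pedigree relationships
#'
#' `Gw = (1 - w) G + w A11`; the default weight 0.05 guarantees a
#' nonsingular genomic matrix.
#'
#' @param G a [RelationshipMatrix] (typically kind `"G_adjusted"`)
#' @param A11 dense pedigree relationships among the genotyped animals
#' @param w blending weight in `[0, 1]`
#' @return a [RelationshipMatrix] of kind `"Gw"`
#' @export
blendG <- function(G, A11, w = 0.05) {
  if (w < 0 || w > 1) stop("blending weight must be in [0, 1]")
  A11 <- as.matrix(A11)
  new("RelationshipMatrix", values = (1 - w) * G@values + w * A11,
      ids = G@ids, kind = "Gw", genotyped = G@genotyped)
}

#' Single-step relationship matrix H (dense block form)
#'
#' Combines pedigree relationships with the blended genomic matrix of the
#' genotyped subset:
#' `H = [Gw, Gw A11inv A12; A12' A11inv Gw, A22 + A12' A11inv (Gw - A11) A11inv A12]`.
#' Row/column order of the result follows the pedigree; the genotyped-first
#' ordering is internal.
#'
#' @param ped a [Pedigree]
#' @param Gw a [RelationshipMatrix] of kind `"Gw"`
#' @return a [RelationshipMatrix] of kind `"H"`
#' @export
assembleH <- function(ped, Gw) {
  f <- ped@frame
  gid <- Gw@ids
  if (!all(gid %in% f$id)) stop("genotyped ids missing from pedigree")
  oth <- setdiff(f$id, gid)
  A <- buildA(ped)@values
  i1 <- as.character(gid); i2 <- as.character(oth)
  A11 <- A[i1, i1, drop = FALSE]
  A12 <- A[i1, i2, drop = FALSE]
  A22 <- A[i2, i2, drop = FALSE]
  A11i <- solve(A11)
  Gwm <- Gw@values
  P <- A11i %*% A12
  H12 <- Gwm %*% P
  H22 <- A22 + t(P) %*% (Gwm - A11) %*% P
  H <- rbind(cbind(Gwm, H12), cbind(t(H12), H22))
  ord <- match(as.character(f$id), c(i1, i2))
  H <- H[ord, ord]
  dimnames(H) <- list(f$id, f$id)
  new("RelationshipMatrix", values = H, ids = f$id, kind = "H",
      genotyped = gid)
}

#' Single-step inverse H^-1
#'
#' The sparse form used in the mixed-model equations:
#' `Hinv = Ainv + [Gw^-1 - A11^-1, 0; 0, 0]` on the genotyped block.
#'
#' @param ainv sparse [buildAinverse()] result for the full pedigree
#' @param Gw a [RelationshipMatrix] of kind `"Gw"`
#' @param A11 dense pedigree relationships among the genotyped animals (in
#'   `Gw@ids` order)
#' @return a [RelationshipMatrix] of kind `"Hinv"` (`inverse = TRUE`)
#' @export
assembleHinverse <- function(ainv, Gw, A11) {
  idx <- match(Gw@ids, ainv@ids)
  if (anyNA(idx)) stop("genotyped ids missing from pedigree")
  delta <- solve(Gw@values) - solve(as.matrix(A11))
  n <- length(ainv@ids)
  q <- length(idx)
  Dm <- Matrix::sparseMatrix(i = rep(idx, q), j = rep(idx, each = q),
                             x = as.numeric(delta), dims = c(n, n))
  M <- Matrix::forceSymmetric(ainv@values + (Dm + Matrix::t(Dm)) / 2)
  new("RelationshipMatrix", values = M, ids = ainv@ids, kind = "Hinv",
      inverse = TRUE, genotyped = Gw@ids)
}
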