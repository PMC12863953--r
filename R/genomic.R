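#' Observed allele frequencies of a genotype matrix
#'
#' @param M animals x SNPs matrix of gene contents 0/1/2 (NA = missing).
#' @return numeric vector of counted-allele frequencies per SNP.
#' @export
allele_freqs <- function(M) {
  colMeans(M, na.rm = TRUE) / 2
}

#' Mean-impute missing genotypes
#'
#' Replaces missing entries of a gene-content matrix by twice the allele
#' frequency of the SNP (the mean gene content), the standard preparation
#' step before building a genomic relationship matrix.
#'
#' @param M animals x SNPs 0/1/2 matrix with possible NAs.
#' @param freqs per-SNP allele frequencies; observed frequencies by default.
#' @return numeric matrix without missing values.
#' @export
impute_genotypes <- function(M, freqs = allele_freqs(M)) {
  if (!anyNA(M)) return(M)
  idx <- which(is.na(M), arr.ind = TRUE)
  M[idx] <- 2 * freqs[idx[, 2]]
  M
}

#' Genomic relationship matrix
#'
#' VanRaden's first method: `G = Z Z' / (2 sum p_i (1 - p_i))` with
#' `Z = M - P`, `P` the matrix of twice the allele frequencies. Missing
#' genotypes are mean-imputed first.
#'
#' @param M animals x SNPs 0/1/2 gene-content matrix (rownames = animal ids).
#' @param freq_source `"observed"` (frequencies counted in `M`) or
#'   `"supplied"` (use `freqs`).
#' @param freqs per-SNP allele frequencies when `freq_source = "supplied"`.
#' @return symmetric matrix with attribute `kind = "G"`.
#' @export
build_G <- function(M, freq_source = c("observed", "supplied"), freqs = NULL) {
  freq_source <- match.arg(freq_source)
  p <- if (freq_source == "observed") allele_freqs(M) else {
    if (is.null(freqs) || length(freqs) != ncol(M))
      stop("freq_source = 'supplied' needs one frequency per SNP")
    freqs
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs fixed: 2*sum(p*(1-p)) = 0, G undefined")
  M <- impute_genotypes(M, p)
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  attr(G, "kind") <- "G"
  G
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' `G_b = w G + (1 - w) A22`. Guarantees invertibility of G before it
#' enters the combined relationship matrix; `w = 0.95` is the customary
#' single-step default.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships among the same (identically ordered)
#'   genotyped animals.
#' @param weight blending weight on G, in (0, 1].
#' @return blended matrix with attribute `kind = "G_blended"`.
#' @export
blend_G <- function(G, A22, weight = 0.95) {
  if (!isTRUE(all.equal(dim(G), dim(A22))) ||
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 must cover identical animal sets in the same order")
  stopifnot(weight >= 0, weight <= 1)
  Gb <- weight * G + (1 - weight) * A22
  attr(Gb, "kind") <- "G_blended"
  Gb
}

#' Inverse of the combined pedigree-genomic relationship matrix
#'
#' Single-step H-inverse: `A^{-1}` plus, on the genotyped x genotyped
#' block, the increment `G^{-1} - A22^{-1}`.
#'
#' @param A_inv sparse or dense inverse of A over all animals
#'   (dimnames required).
#' @param G_inv inverse of the (blended) genomic matrix.
#' @param A22_inv inverse of the pedigree relationships among genotyped
#'   animals, ordered identically to `G_inv`.
#' @param genotyped_ids animal ids of the genotyped block, in the order of
#'   `G_inv` rows.
#' @return symmetric sparse matrix (class `dgCMatrix`) with `kind` attribute
#'   `"Hinv"`.
#' @export
build_H_inverse <- function(A_inv, G_inv, A22_inv, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  if (!all(genotyped_ids %in% rownames(A_inv)))
    stop("genotyped ids absent from A-inverse: ",
         paste(utils::head(setdiff(genotyped_ids, rownames(A_inv)), 5), collapse = ", "))
  if (length(genotyped_ids)) {
    if (!identical(dim(G_inv), dim(A22_inv)) ||
        any(dim(G_inv) != length(genotyped_ids)))
      stop("G_inv and A22_inv must be square over the genotyped ids")
  }
  Hinv <- methods::as(Matrix::Matrix(A_inv, sparse = TRUE), "generalMatrix")
  if (length(genotyped_ids)) {
    idx <- match(genotyped_ids, rownames(A_inv))
    Hinv[idx, idx] <- Hinv[idx, idx] + (G_inv - A22_inv)
  }
  Hinv <- methods::as((Hinv + Matrix::t(Hinv)) / 2, "CsparseMatrix")
  attr(Hinv, "kind") <- "Hinv"
  Hinv
}

#' Assemble H-inverse from a pedigree and a genotype matrix
#'
#' Convenience wrapper running the full chain: A-inverse (sparse,
#' Henderson's rules), A22 as the genotyped block of the tabular A over the
#' full pedigree, G from the genotypes, blending, dense inversion of the
#' small genotyped-block matrices, and assembly of the combined inverse.
#'
#' @param ped a [as_pedigree()] object covering all evaluated animals.
#' @param M genotype matrix whose rownames are a subset of the pedigree.
#' @param blend_weight weight on G in [blend_G()].
#' @param freq_source passed to [build_G()].
#' @return list with elements `Hinv`, `G`, `G_blended`, `A22`,
#'   `genotyped_ids`.
#' @export
make_H_inverse <- function(ped, M, blend_weight = 0.95,
                           freq_source = "observed") {
  ped <- as_pedigree(ped)
  gids <- rownames(M)
  if (is.null(gids) || !all(gids %in% ped$animal))
    stop("genotyped animals must appear in the pedigree")
  Ainv <- build_A_inverse(ped)
  A <- build_A(ped)
  A22 <- A[gids, gids, drop = FALSE]
  G <- build_G(M, freq_source = freq_source)
  Gb <- blend_G(G, A22, weight = blend_weight)
  Ginv <- tryCatch(solve(Gb), error = function(e)
    stop("blended G is singular; lower blend_weight (got ", blend_weight, ")"))
  A22inv <- solve(A22)
  Hinv <- build_H_inverse(Ainv, Ginv, A22inv, gids)
  list(Hinv = Hinv, G = G, G_blended = Gb, A22 = A22, genotyped_ids = gids)
}
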