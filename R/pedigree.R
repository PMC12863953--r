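#' Validate and order a pedigree
#'
#' Builds a `pedigree` object from animal/sire/dam triplets. Unknown parents
#' are coded `0` (or `NA`). Records are topologically sorted so that parents
#' precede their offspring; if the input had to be reordered a warning is
#' issued. A cyclic pedigree (an animal that is its own ancestor) is rejected.
#'
#' @param x data.frame with columns `animal`, `sire`, `dam` (ids; `0`/`NA`
#'   means unknown). An optional `generation` column is carried through.
#' @return A data.frame of class `pedigree` with character id columns
#'   `animal`, `sire`, `dam`, integer index columns `sire_idx`, `dam_idx`
#'   (0 = unknown) and, when derivable or supplied, a `generation` column.
#' @export
as_pedigree <- function(x) {
  if (inherits(x, "pedigree") && !is.null(x$sire_idx)) return(x)
  stopifnot(is.data.frame(x))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns 'animal', 'sire', 'dam'")
  ped <- data.frame(animal = as.character(x$animal),
                    sire   = as.character(x$sire),
                    dam    = as.character(x$dam),
                    stringsAsFactors = FALSE)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  if (anyNA(ped$animal) || any(ped$animal == "0"))
    stop("animal ids must be non-missing and distinct from the unknown code '0'")
  if (anyDuplicated(ped$animal))
    stop("duplicated animal ids: ", paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  unknown_parents <- setdiff(union(ped$sire, ped$dam), c("0", ped$animal))
  if (length(unknown_parents))
    stop("parents absent from the animal column: ", paste(utils::head(unknown_parents, 5), collapse = ", "))
  if (any(ped$sire == ped$animal) || any(ped$dam == ped$animal))
    stop("an animal cannot be its own parent")

  pos <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  ordered <- all(si < pos, na.rm = TRUE) && all(di < pos, na.rm = TRUE)
  if (!ordered) {
    ord <- .pedigree_topo_order(ped)
    if (is.null(ord)) stop("cyclic pedigree: an animal is its own ancestor")
    warning("pedigree reordered so parents precede offspring")
    ped <- ped[ord, , drop = FALSE]
    rownames(ped) <- NULL
  }
  ped$sire_idx <- ifelse(ped$sire == "0", 0L, match(ped$sire, ped$animal))
  ped$dam_idx  <- ifelse(ped$dam == "0", 0L, match(ped$dam, ped$animal))
  if ("generation" %in% names(x)) {
    gen <- x$generation[match(ped$animal, as.character(x$animal))]
    ped$generation <- as.integer(gen)
  } else {
    gen <- integer(nrow(ped))
    for (i in seq_len(nrow(ped))) {
      g <- 0L
      if (ped$sire_idx[i] > 0L) g <- max(g, gen[ped$sire_idx[i]] + 1L)
      if (ped$dam_idx[i] > 0L) g <- max(g, gen[ped$dam_idx[i]] + 1L)
      gen[i] <- g
    }
    ped$generation <- gen
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; NULL on cycle.
.pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)  # NA = unknown
  di <- match(ped$dam, id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) return(NULL)
  out
}

#' Truncate a pedigree to a fixed number of ancestral generations
#'
#' Keeps a set of anchor animals (typically all phenotyped and/or genotyped
#' animals) plus their ancestors up to `n_generations` back. Parents that
#' fall outside the horizon are recoded unknown. Matches routine evaluation
#' practice of restricting deep historical pedigrees to a few generations.
#'
#' @param ped a [as_pedigree()] object.
#' @param n_generations number of ancestral generations to retain behind the
#'   anchors (0 keeps the anchors only).
#' @param anchors character vector of animal ids; defaults to all animals.
#' @return the truncated `pedigree`.
#' @export
truncate_pedigree <- function(ped, n_generations = 3, anchors = ped$animal) {
  ped <- as_pedigree(ped)
  anchors <- as.character(anchors)
  missing_anchors <- setdiff(anchors, ped$animal)
  if (length(missing_anchors))
    stop("anchors absent from pedigree: ", paste(utils::head(missing_anchors, 5), collapse = ", "))
  depth <- rep(Inf, nrow(ped))
  depth[match(anchors, ped$animal)] <- 0
  # walk offspring -> parents; reverse pedigree order visits offspring first
  for (i in rev(seq_len(nrow(ped)))) {
    if (!is.finite(depth[i])) next
    for (p in c(ped$sire_idx[i], ped$dam_idx[i])) {
      if (p > 0L) depth[p] <- min(depth[p], depth[i] + 1)
    }
  }
  keep <- which(depth <= n_generations)
  out <- data.frame(animal = ped$animal[keep], sire = ped$sire[keep],
                    dam = ped$dam[keep], stringsAsFactors = FALSE)
  kept_ids <- out$animal
  out$sire[!(out$sire %in% kept_ids)] <- "0"
  out$dam[!(out$dam %in% kept_ids)] <- "0"
  # parents of animals sitting exactly on the horizon are recoded unknown
  on_horizon <- depth[keep] == n_generations
  out$sire[on_horizon] <- "0"
  out$dam[on_horizon] <- "0"
  rownames(out) <- NULL
  as_pedigree(out)
}

#' Numerator relationship matrix (A) by the tabular method
#'
#' Recursive (tabular) construction of Wright's numerator relationship
#' matrix with inbreeding: `a_ij = 0.5 (a_j,sire(i) + a_j,dam(i))` and
#' `a_ii = 1 + F_i` with `F_i = 0.5 a_sire(i),dam(i)`.
#'
#' @param ped a [as_pedigree()] object.
#' @return symmetric numeric matrix with animal ids as dimnames and
#'   attribute `kind = "A"`.
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(ped)
  A <- .tabular_A(ped$sire_idx, ped$dam_idx)
  dimnames(A) <- list(ped$animal, ped$animal)
  attr(A, "kind") <- "A"
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a [as_pedigree()] object.
#' @return named numeric vector of F coefficients (diagonal of A minus 1).
#' @export
inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  f <- .inbreeding_from_pedigree(ped$sire_idx, ped$dam_idx)
  names(f) <- ped$animal
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct sparse construction of A-inverse by Henderson's rules with
#' inbreeding: for each animal the Mendelian-sampling precision
#' `1 / (a_ii - 0.25 (a_ss + a_dd))` is scattered onto the
#' animal/sire/dam block. Exact (equals `solve(build_A(ped))`) for any
#' pedigree; kept sparse so the Gibbs sampler can exploit the structure
#' of H-inverse outside the genotyped block.
#'
#' @param ped a [as_pedigree()] object.
#' @return a symmetric [Matrix::dgCMatrix-class] with animal id dimnames.
#' @export
build_A_inverse <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  f <- .inbreeding_from_pedigree(ped$sire_idx, ped$dam_idx)
  dii <- 1 + f  # a_ii
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    # Mendelian-sampling variance: 1 - 0.25 (a_ss + a_dd), an unknown
    # parent contributing 0 -- the animal's own inbreeding does not enter
    denom <- 1 - 0.25 * ((if (s > 0) dii[s] else 0) + (if (d > 0) dii[d] else 0))
    alpha <- 1 / denom
    add(i, i, alpha)
    for (p in c(s, d)) {
      if (p > 0) {
        add(i, p, -alpha / 2); add(p, i, -alpha / 2)
        add(p, p, alpha / 4)
      }
    }
    if (s > 0 && d > 0) {
      add(s, d, alpha / 4); add(d, s, alpha / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  methods::as(Ainv, "generalMatrix")
}
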