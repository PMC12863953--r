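#' Build contemporary-group labels from factor columns
#'
#' Concatenates the stated factor columns, in order, into one opaque CG
#' label per record (separator `"|"`). Records with a missing factor value
#' are excluded and listed in the `excluded` attribute.
#'
#' @param records data.frame of phenotype records with an `animal` column.
#' @param factor_columns character vector of column names defining the CG
#'   (e.g. year/season of birth, sex, farm).
#' @param sep reserved separator, must not occur in the factor values.
#' @return data.frame (animal, cg) with attribute `excluded` (animal ids
#'   dropped for missing factors).
#' @export
build_contemporary_groups <- function(records, factor_columns, sep = "|") {
  stopifnot(is.data.frame(records), "animal" %in% names(records))
  missing_cols <- setdiff(factor_columns, names(records))
  if (length(missing_cols))
    stop("factor columns absent: ", paste(missing_cols, collapse = ", "))
  vals <- lapply(records[factor_columns], as.character)
  if (any(vapply(vals, function(v) any(grepl(sep, v, fixed = TRUE)), logical(1))))
    stop("separator '", sep, "' occurs inside a factor value")
  bad <- Reduce(`|`, lapply(vals, is.na))
  if (any(bad))
    message(sum(bad), " record(s) excluded for missing CG factors")
  lab <- do.call(paste, c(vals, sep = sep))
  out <- data.frame(animal = as.character(records$animal)[!bad],
                    cg = lab[!bad], stringsAsFactors = FALSE)
  attr(out, "excluded") <- as.character(records$animal)[bad]
  out
}

.new_qc_report <- function() {
  structure(list(cg_removed_size = 0L, cg_removed_novar = 0L,
                 cg_removed_disconnected = 0L,
                 records_removed = 0L,
                 snps_removed_hwe = 0L, snps_removed_callrate = 0L,
                 snps_removed_maf = 0L,
                 animals_removed_callrate = 0L,
                 n_cgs_in = NA_integer_, n_cgs_out = NA_integer_,
                 n_records_in = NA_integer_, n_records_out = NA_integer_,
                 n_snps_in = NA_integer_, n_snps_out = NA_integer_),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (nm in names(x)) if (!is.na(x[[nm]])) cat(sprintf("  %-28s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Serialize a QC report as JSON
#' @param report a `qc_report`.
#' @param path optional file to write to.
#' @return JSON string, invisibly when written to file.
#' @export
qc_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Filter contemporary groups by size and phenotypic variability
#'
#' Removes every CG with fewer than `min_size` phenotyped animals and every
#' CG whose records are all 0 or all 1 (no variability), the two standard
#' phenotypic-QC exclusions for binary traits.
#'
#' @param phenotypes data.frame (animal, cg, y) with y coded 0/1.
#' @param min_size minimum CG size (default 10).
#' @param report an existing `qc_report` to update.
#' @return list(phenotypes, report).
#' @export
filter_cgs <- function(phenotypes, min_size = 10, report = .new_qc_report()) {
  stopifnot(all(c("animal", "cg", "y") %in% names(phenotypes)))
  if (!all(phenotypes$y %in% c(0, 1)))
    stop("phenotypes must be coded 0/1")
  report$n_records_in <- nrow(phenotypes)
  report$n_cgs_in <- length(unique(phenotypes$cg))
  size <- table(phenotypes$cg)
  small <- names(size)[size < min_size]
  report$cg_removed_size <- report$cg_removed_size + length(small)
  keep <- !(phenotypes$cg %in% small)
  phenotypes <- phenotypes[keep, , drop = FALSE]
  novar <- names(which(tapply(phenotypes$y, phenotypes$cg, function(v)
    all(v == 0) || all(v == 1))))
  report$cg_removed_novar <- report$cg_removed_novar + length(novar)
  phenotypes <- phenotypes[!(phenotypes$cg %in% novar), , drop = FALSE]
  report$n_records_out <- nrow(phenotypes)
  report$n_cgs_out <- length(unique(phenotypes$cg))
  report$records_removed <- report$n_records_in - report$n_records_out
  if (nrow(phenotypes) == 0)
    stop("no analyzable data: every contemporary group was removed")
  rownames(phenotypes) <- NULL
  list(phenotypes = phenotypes, report = report)
}

#' Keep only the largest sire-connected cluster of contemporary groups
#'
#' Builds a graph with CGs as nodes; two CGs are joined when they share at
#' least `min_links` sires of phenotyped animals. Only records in the
#' largest connected component are retained, an internal stand-in for the
#' usual connectedness verification of genetic-evaluation pipelines.
#' Records whose animal is absent from the pedigree are excluded first.
#'
#' @param phenotypes data.frame (animal, cg, y).
#' @param ped a [as_pedigree()] object covering the phenotyped animals.
#' @param min_links minimum number of shared sires defining an edge.
#' @param report an existing `qc_report` to update.
#' @return list(phenotypes, report).
#' @export
check_connectedness <- function(phenotypes, ped, min_links = 1,
                                report = .new_qc_report()) {
  ped <- as_pedigree(ped)
  n_in <- nrow(phenotypes)
  in_ped <- phenotypes$animal %in% ped$animal
  if (!all(in_ped))
    message(sum(!in_ped), " record(s) excluded: animal not in pedigree")
  phenotypes <- phenotypes[in_ped, , drop = FALSE]
  sire <- ped$sire[match(phenotypes$animal, ped$animal)]
  cgs <- sort(unique(phenotypes$cg))
  k <- length(cgs)
  comp <- seq_len(k)                      # union-find over CGs
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  sire_sets <- lapply(cgs, function(g)
    unique(sire[phenotypes$cg == g & sire != "0"]))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (length(intersect(sire_sets[[i]], sire_sets[[j]])) >= min_links) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  sizes <- tapply(as.integer(table(phenotypes$cg)[cgs]), root, sum)
  main <- as.integer(names(sizes)[which.max(sizes)])
  keep_cgs <- cgs[root == main]
  removed <- setdiff(cgs, keep_cgs)
  report$cg_removed_disconnected <- report$cg_removed_disconnected + length(removed)
  phenotypes <- phenotypes[phenotypes$cg %in% keep_cgs, , drop = FALSE]
  report$records_removed <- report$records_removed + (n_in - nrow(phenotypes))
  rownames(phenotypes) <- NULL
  list(phenotypes = phenotypes, report = report)
}

#' SNP quality control
#'
#' Removes SNPs failing a one-degree-of-freedom Hardy-Weinberg chi-square
#' test at `hwe_p`, a call-rate threshold, or a minor-allele-frequency
#' threshold. An animal call-rate filter is available but off by default.
#'
#' @param M animals x SNPs 0/1/2 matrix, NA = missing.
#' @param hwe_p HWE p-value threshold (default 1e-15).
#' @param call_rate minimum SNP call rate (default 0.90).
#' @param maf minimum minor allele frequency (default 0.02).
#' @param animal_call_rate optional minimum per-animal call rate (NULL = off).
#' @param report an existing `qc_report` to update.
#' @return list(genotypes, report).
#' @export
genotype_qc <- function(M, hwe_p = 1e-15, call_rate = 0.90, maf = 0.02,
                        animal_call_rate = NULL, report = .new_qc_report()) {
  ok_vals <- M %in% c(0L, 1L, 2L) | is.na(M)
  if (!all(ok_vals)) stop("genotype entries must be 0/1/2 or missing")
  report$n_snps_in <- ncol(M)
  if (!is.null(animal_call_rate)) {
    acr <- rowMeans(!is.na(M))
    drop_a <- acr < animal_call_rate
    report$animals_removed_callrate <- sum(drop_a)
    M <- M[!drop_a, , drop = FALSE]
  }
  cr <- colMeans(!is.na(M))
  p <- allele_freqs(M)
  mafs <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(ncol(M)), function(j) .hwe_pvalue(M[, j]), numeric(1))
  fail_cr <- cr < call_rate
  fail_maf <- !fail_cr & mafs < maf
  fail_hwe <- !fail_cr & !fail_maf & hwe < hwe_p
  report$snps_removed_callrate <- report$snps_removed_callrate + sum(fail_cr)
  report$snps_removed_maf <- report$snps_removed_maf + sum(fail_maf)
  report$snps_removed_hwe <- report$snps_removed_hwe + sum(fail_hwe)
  keep <- !(fail_cr | fail_maf | fail_hwe)
  report$n_snps_out <- sum(keep)
  if (!any(keep)) stop("genotype QC removed every SNP")
  list(genotypes = M[, keep, drop = FALSE], report = report)
}

# 1-df chi-square HWE test against expected genotype counts at the
# observed allele frequency; NA entries ignored.
.hwe_pvalue <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0) return(NA_real_)
  p <- mean(g) / 2
  if (p <= 0 || p >= 1) return(1)  # monomorphic: HWE trivially satisfied
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
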