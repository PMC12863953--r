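# ---- provenance headers -----------------------------------------------

.write_with_header <- function(df, path, headers, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(headers))
    writeLines(sprintf("#%s=%s", nm, headers[[nm]]), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_headers <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr)) return(list())
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1))
}

# FNV-1a over the serialized config; enough to fingerprint a run.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

# ---- readers / writers -------------------------------------------------

#' Read a pedigree CSV
#'
#' Dialect: header `animal,sire,dam`, `0` = unknown parent, `#`-prefixed
#' provenance lines allowed. Offspring listed before their parents are
#' repaired by topological sorting (with a warning); cycles are rejected.
#'
#' @param path file path.
#' @return a [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  if (!all(c("animal", "sire", "dam") %in% names(df)))
    stop("pedigree file needs header 'animal,sire,dam': ", path)
  as_pedigree(df)
}

#' Write a pedigree CSV
#' @param ped a [as_pedigree()] object.
#' @param path file path.
#' @param headers named list of provenance key=value lines.
#' @return the path, invisibly.
#' @export
write_pedigree <- function(ped, path, headers = list(stage = "pedigree")) {
  ped <- as_pedigree(ped)
  .write_with_header(ped[, c("animal", "sire", "dam")], path, headers)
}

#' Read a phenotype CSV
#'
#' Dialect: header `animal,cg,<trait>` with 0/1/NA records; the trait
#' column (third by default) is standardized to `y` and missing records
#' are dropped.
#'
#' @param path file path.
#' @param trait trait column name (default: the third column).
#' @return data.frame (animal, cg, y).
#' @export
read_phenotypes <- function(path, trait = NULL) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(animal = "character", cg = "character"))
  if (!all(c("animal", "cg") %in% names(df)))
    stop("phenotype file needs columns 'animal' and 'cg': ", path)
  if (is.null(trait)) trait <- setdiff(names(df), c("animal", "cg"))[1]
  if (is.na(trait) || !trait %in% names(df))
    stop("trait column not found in ", path)
  y <- df[[trait]]
  if (!all(y %in% c(0, 1) | is.na(y)))
    stop("trait column '", trait, "' must be 0/1/NA")
  out <- data.frame(animal = df$animal, cg = df$cg, y = as.integer(y),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$y), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  out
}

#' Write a phenotype CSV
#' @param phenotypes data.frame (animal, cg, y).
#' @param path file path.
#' @param trait column name used for the trait in the file.
#' @param headers named list of provenance key=value lines.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, trait = "defect",
                             headers = list(stage = "phenotypes")) {
  df <- data.frame(animal = phenotypes$animal, cg = phenotypes$cg,
                   y = phenotypes$y)
  names(df)[3] <- trait
  .write_with_header(df, path, headers)
}

#' Read a genotype matrix
#'
#' Dialect: whitespace-delimited, a header row of SNP ids, first column
#' the animal id, remaining entries 0/1/2/NA (a PLINK-RAW-compatible
#' subset). Invalid entries are rejected with their line and column.
#'
#' @param path file path.
#' @return integer matrix animals x SNPs with dimnames.
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop("genotype file has no data rows: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  snps <- fields[[1]][-1]
  rows <- fields[-1]
  ids <- vapply(rows, `[[`, "", 1)
  M <- matrix(NA_integer_, length(rows), length(snps),
              dimnames = list(ids, snps))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1]
    if (length(vals) != length(snps))
      stop("line ", i + 1, ": expected ", length(snps), " genotypes, got ",
           length(vals))
    bad <- !(vals %in% c("0", "1", "2", "NA"))
    if (any(bad))
      stop("line ", i + 1, ", column ", which(bad)[1] + 1,
           ": invalid genotype '", vals[which(bad)[1]], "'")
    M[i, ] <- suppressWarnings(as.integer(vals))
  }
  M
}

#' Write a genotype matrix
#' @param M animals x SNPs 0/1/2 matrix.
#' @param path file path.
#' @param headers named list of provenance key=value lines.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(M, path, headers = list(stage = "genotypes")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(headers))
    writeLines(sprintf("#%s=%s", nm, headers[[nm]]), con)
  writeLines(paste(c("animal", colnames(M)), collapse = "\t"), con)
  body <- apply(M, 1, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(M), body, sep = "\t"), con)
  invisible(path)
}

#' Write a GEBV table
#'
#' Tab-separated `animal  model  scale  value` with provenance headers.
#'
#' @param gebv GEBV table.
#' @param path file path.
#' @param headers named list of provenance key=value lines.
#' @return the path, invisibly.
#' @export
write_gebv_table <- function(gebv, path, headers = list(stage = "gebv")) {
  cols <- intersect(c("animal", "model", "scale", "value"), names(gebv))
  .write_with_header(gebv[, cols], path, headers, sep = "\t")
}

#' Read a GEBV table written by [write_gebv_table()]
#' @param path file path.
#' @return GEBV data.frame; provenance headers in attribute `headers`.
#' @export
read_gebv_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(animal = "character"))
  attr(df, "headers") <- .read_headers(path)
  df
}

#' Write population truth values for parameter-recovery checks
#' @param pop a `sim_population`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_truth <- function(pop, path) {
  stopifnot(inherits(pop, "sim_population"))
  df <- data.frame(animal = names(pop$true_bv),
                   true_bv = as.numeric(pop$true_bv),
                   liability = as.numeric(pop$liabilities[names(pop$true_bv)]))
  hdr <- as.list(stats::setNames(as.character(pop$true_params),
                                 names(pop$true_params)))
  .write_with_header(df, path, c(list(stage = "truth"), hdr), sep = "\t")
}

# ---- pipeline ----------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the QC thresholds, relationship options, sampler settings and
#' comparison options of the full evaluation pipeline. When `pedigree`,
#' `phenotypes` and `genotypes` paths are NULL, a synthetic population is
#' generated from `sim` instead.
#'
#' @param pedigree,phenotypes,genotypes input file paths, or NULL to
#'   simulate.
#' @param sim a [sim_config()] used when simulating.
#' @param trait trait name used in output files.
#' @param cg_min_size,min_links,hwe_p,call_rate,maf QC thresholds.
#' @param generations pedigree truncation depth.
#' @param blend_weight blending weight on G.
#' @param models character vector among `"linear"`, `"threshold"`.
#' @param n_iterations,burn_in,thin,seed sampler settings.
#' @param transformation `"threshold_density"` or
#'   `"variance_heritability"` for the observed-to-liability step.
#' @param selection_fraction,min_offspring comparison options.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pedigree = NULL, phenotypes = NULL,
                            genotypes = NULL,
                            sim = sim_config(),
                            trait = "defect",
                            cg_min_size = 10, min_links = 1,
                            hwe_p = 1e-15, call_rate = 0.90, maf = 0.02,
                            generations = 3, blend_weight = 0.95,
                            models = c("linear", "threshold"),
                            n_iterations = 50000, burn_in = 10000, thin = 50,
                            seed = 1L,
                            transformation = c("threshold_density",
                                               "variance_heritability"),
                            selection_fraction = 0.10, min_offspring = 10) {
  transformation <- match.arg(transformation)
  models <- match.arg(models, several.ok = TRUE)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full evaluation pipeline
#'
#' Simulate or ingest -> phenotypic and genomic QC -> relationship
#' matrices -> Gibbs fits of the requested models -> convergence
#' diagnostics -> scale transformations -> sire concordance. All artifacts
#' are written under `out_dir` with provenance headers; a JSON manifest
#' records the seed and a config fingerprint.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results (qc report,
#'   posterior summaries, GEBV tables per scale, diagnostics, concordance).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config[setdiff(names(config), "sim")])
  hdr <- list(config_hash = hash, seed = config$seed)
  stage <- "input"
  res <- list()
  tryCatch({
    # -- ingest or simulate
    if (is.null(config$pedigree)) {
      pop <- simulate_population(config$sim)
      ped <- pop$pedigree
      phen <- pop$phenotypes
      M <- pop$genotypes
      write_truth(pop, file.path(out_dir, "truth.tsv"))
    } else {
      ped <- read_pedigree(config$pedigree)
      phen <- read_phenotypes(config$phenotypes, trait = NULL)
      M <- if (is.null(config$genotypes)) NULL else read_genotypes(config$genotypes)
    }

    # -- phenotypic QC
    stage <- "qc"
    f1 <- filter_cgs(phen, min_size = config$cg_min_size)
    f2 <- check_connectedness(f1$phenotypes, ped,
                              min_links = config$min_links,
                              report = f1$report)
    phen <- f2$phenotypes
    report <- f2$report
    if (!is.null(M)) {
      g <- genotype_qc(M, hwe_p = config$hwe_p, call_rate = config$call_rate,
                       maf = config$maf, report = report)
      M <- g$genotypes
      report <- g$report
    }
    qc_report_json(report, file.path(out_dir, "qc_report.json"))

    # -- relationships
    stage <- "relationships"
    anchors <- union(phen$animal, rownames(M))
    ped_use <- truncate_pedigree(ped, n_generations = config$generations,
                                 anchors = anchors)
    if (!is.null(M)) {
      M <- M[rownames(M) %in% ped_use$animal, , drop = FALSE]
      rel <- make_H_inverse(ped_use, M, blend_weight = config$blend_weight)
      Hinv <- rel$Hinv
    } else {
      Hinv <- build_A_inverse(ped_use)
    }

    # -- model fits
    stage <- "mcmc"
    design <- model_design(phen, Hinv)
    alpha_hat <- mean(phen$y)
    fits <- list()
    for (m in config$models) {
      spec <- model_spec(model_type = m, n_iterations = config$n_iterations,
                         burn_in = config$burn_in, thin = config$thin,
                         seed = config$seed)
      chain <- run_gibbs(design, spec)
      summ <- summarize_chain(chain)
      diag <- diagnose_chain(chain)
      jsonlite::write_json(diag, file.path(out_dir, paste0("diagnostics_", m, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
      fits[[m]] <- list(chain = chain, summary = summ, diagnostics = diag)
    }

    # -- scale transformations
    stage <- "scales"
    gebv_tables <- list()
    for (m in names(fits)) {
      summ <- fits[[m]]$summary
      g0 <- summ$gebv
      if (m == "linear") {
        h2_o <- summ$params$mean[summ$params$parameter == "h2"]
        h2_l <- h2_observed_to_liability(h2_o, alpha_hat)
        gl <- if (config$transformation == "threshold_density")
          gebv_threshold_density_adjust(g0, h2_o, h2_l, alpha_hat)
        else gebv_var_heritability_adjust(
          g0, summ$params$mean[summ$params$parameter == "sigma2e"], h2_o, h2_l)
        gl$model <- m
      } else {
        gl <- g0
      }
      gp <- gebv_to_probability(gl, alpha_hat)
      gebv_tables[[m]] <- list(observed = if (m == "linear") g0 else NULL,
                               liability = gl, probability = gp)
      write_gebv_table(rbind(gl, gp),
                       file.path(out_dir, paste0("gebv_", m, ".tsv")),
                       headers = c(hdr, list(stage = "gebv", model = m,
                                             alpha = alpha_hat)))
    }

    # -- comparison
    stage <- "compare"
    comp <- NULL
    if (all(c("linear", "threshold") %in% names(fits))) {
      sires <- eligible_sires(ped_use, phen,
                              min_offspring = config$min_offspring)
      elig <- sires$sire[sires$eligible]
      if (length(elig) >= 3) {
        ga <- gebv_tables$linear$probability
        gb <- gebv_tables$threshold$probability
        ga <- ga[ga$animal %in% elig, ]
        gb <- gb[gb$animal %in% elig, ]
        sa <- select_top(ga, fraction = config$selection_fraction)
        sb <- select_top(gb, fraction = config$selection_fraction)
        comp <- concordance(sa, sb, elig, ga, gb)
        jsonlite::write_json(unclass(comp),
                             file.path(out_dir, "concordance.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
      }
    }

    manifest <- list(package_version = as.character(utils::packageVersion("defectEval")),
                     seed = config$seed, config_hash = hash,
                     alpha_realized = alpha_hat,
                     stages = c("input", "qc", "relationships", "mcmc",
                                "scales", "compare"),
                     status = "complete")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res <- list(qc_report = report,
                fits = lapply(fits, function(f) f["summary"]),
                gebv = gebv_tables, concordance = comp,
                diagnostics = lapply(fits, function(f) f$diagnostics),
                alpha_realized = alpha_hat, manifest = manifest)
  }, error = function(e) {
    jsonlite::write_json(list(status = "failed", stage = stage,
                              error = conditionMessage(e),
                              config_hash = hash),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
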