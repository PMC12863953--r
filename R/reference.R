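#' Published summary statistics for Nellore morphological defects
#'
#' Per-trait counts and liability-scale heritabilities from a large
#' commercial Nellore genetic evaluation of seven binary morphological
#' defects (records collected 1998-2021): total phenotyped animals and
#' affected animals after phenotypic quality control, number of
#' contemporary groups, the posterior-mean liability-scale heritability of
#' the threshold model, and the sire-validation bookkeeping (eligible
#' sires with >= 10 phenotyped offspring and the number selected by both
#' models in the top-10% comparison). These published numbers are inputs
#' for worked examples: prevalence computation, heritability scale
#' conversion, and selection-concordance accounting.
#'
#' @return data.frame with columns `trait`, `n_animals`, `n_affected`,
#'   `n_cgs`, `h2_liability`, `h2_observed_threshold` (the published
#'   converted value), `n_sires`, `both_selected`.
#' @export
defect_reference <- function() {
  data.frame(
    trait = c("depigmentation", "feet_legs", "chamfer", "loin",
              "hump", "jaw", "navel"),
    n_animals = c(182964L, 108782L, 118354L, 81818L, 60188L, 38105L, 13745L),
    n_affected = c(11310L, 8098L, 5972L, 3894L, 3363L, 1613L, 665L),
    n_cgs = c(5629L, 3534L, 3628L, 2488L, 1857L, 1201L, 456L),
    h2_liability = c(0.54, 0.23, 0.18, 0.37, 0.35, 0.26, 0.50),
    h2_observed_threshold = c(0.12, 0.06, 0.04, 0.07, 0.08, 0.05, 0.10),
    n_sires = c(1338L, 987L, 1050L, 804L, 637L, 463L, 219L),
    both_selected = c(106L, 24L, 74L, 65L, 47L, 31L, 17L),
    stringsAsFactors = FALSE
  )
}
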