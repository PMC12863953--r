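# Small pedigrees and populations shared across test files.

# unrelated sire/dam, two full sibs, one half sib through the sire
ped_family <- function() {
  as_pedigree(data.frame(
    animal = c("s", "d", "d2", "o1", "o2", "h1"),
    sire = c("0", "0", "0", "s", "s", "s"),
    dam = c("0", "0", "0", "d", "d", "d2"),
    stringsAsFactors = FALSE))
}

# full-sib mating: x is inbred with F = 0.25
ped_inbred <- function() {
  as_pedigree(data.frame(
    animal = c("s", "d", "a", "b", "x"),
    sire = c("0", "0", "s", "s", "a"),
    dam = c("0", "0", "d", "d", "b"),
    stringsAsFactors = FALSE))
}

# standard small synthetic population used by several modules
small_population <- function(seed = 7, n_founders = 100, n_generations = 2,
                             h2 = 0.35, alpha = 0.10, n_snps = 200) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_snps = n_snps, h2_liability = h2, prevalence = alpha,
                    n_cgs = 4, prop_genotyped = 0.3, seed = seed)
  simulate_population(cfg)
}

# GEBV table from a named numeric vector
gebv_table <- function(values, model = "linear", scale = "observed") {
  data.frame(animal = names(values), model = model, scale = scale,
             value = as.numeric(values), stringsAsFactors = FALSE)
}
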