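#' Molecular clock configuration
#'
#' Holds the two clocks used for node dating: the overall protein-coding
#' rate (substitutions per site per year) and the synonymous rate
#' (synonymous mutations per codon per year, i.e. counted per codon, not per
#' position). Genome sizes (`coding_sites`, `coding_codons`) are supplied by
#' the user, typically from the loaded reference annotation; the shipped
#' presets carry rates only.
#'
#' @param protein_coding_rate substitutions per site per year (> 0).
#' @param synonymous_rate synonymous mutations per codon per year (> 0).
#' @param coding_sites number of protein-coding sites in the genome.
#' @param coding_codons number of protein-coding codons in the genome.
#' @param species optional label.
#' @return An object of class `clock_config`.
#' @export
clock_config <- function(protein_coding_rate, synonymous_rate,
                         coding_sites, coding_codons, species = NULL) {
  stopifnot(protein_coding_rate > 0, synonymous_rate > 0,
            coding_sites > 0, coding_codons > 0)
  structure(list(species = species,
                 protein_coding_rate = protein_coding_rate,
                 synonymous_rate = synonymous_rate,
                 coding_sites = coding_sites,
                 coding_codons = coding_codons),
            class = "clock_config")
}

#' Maximum-likelihood mutation-rate presets
#'
#' Published strict-clock maximum-likelihood rate estimates for six
#' mammalian species groups: overall protein-coding substitution rates (per
#' nucleotide site per year, with standard errors) and synonymous rates (per
#' codon per year, with standard errors). The mean waiting times between
#' mutations over the whole coding region, as published alongside the rates,
#' are included for reference.
#'
#' @return data frame with one row per species preset
#'   (`homo_pan`, `canis`, `bos`, `sus`, `orcinus`, `mus`).
#' @export
clock_presets <- function() {
  data.frame(
    preset = c("homo_pan", "canis", "bos", "sus", "orcinus", "mus"),
    species = c("Homo sapiens/Pan troglodytes/Pan paniscus", "Canis lupus",
                "Bos taurus/Bos grunniens/Bison bison", "Sus scrofa",
                "Orcinus orca", "Mus musculus"),
    protein_coding_rate = c(1.29e-8, 9.68e-9, 9.00e-9, 1.18e-8, 1.22e-8,
                            2.78e-8),
    protein_coding_se = c(4.99e-10, 4.52e-10, 3.66e-10, 5.87e-10, 1.49e-9,
                          2.13e-9),
    synonymous_rate = c(3.27e-8, 2.45e-8, 2.12e-8, 2.90e-8, 2.66e-8,
                        7.72e-8),
    synonymous_se = c(5.55e-9, 1.06e-9, 8.33e-10, 4.90e-9, 8.69e-10,
                      3.91e-9),
    years_per_mutation = c(6790, 9026, 9708, 7424, 7143, 3035),
    years_per_syn_mutation = c(8027, 10684, 12393, 8742, 9842, 3396),
    stringsAsFactors = FALSE)
}

#' @rdname clock_config
#' @param preset preset name from [clock_presets()].
#' @export
clock_preset <- function(preset, coding_sites, coding_codons) {
  tab <- clock_presets()
  i <- match(preset, tab$preset)
  if (is.na(i)) stop("unknown preset '", preset, "'; available: ",
                     paste(tab$preset, collapse = ", "))
  clock_config(tab$protein_coding_rate[i], tab$synonymous_rate[i],
               coding_sites, coding_codons, species = tab$species[i])
}

#' Convert a per-codon rate to a per-site rate
#'
#' A rate expressed per codon per year divided by the three positions of the
#' codon gives the per-site equivalent.
#'
#' @param rate_per_codon numeric rate per codon per year.
#' @return rate per site per year.
#' @export
per_codon_to_per_site <- function(rate_per_codon) rate_per_codon / 3

#' Mean years between mutations under a clock
#'
#' @param clock a [clock_config()].
#' @return `years_per_mutation()`: `1 / (protein_coding_rate * coding_sites)`;
#'   `years_per_syn_mutation()`: `1 / (synonymous_rate * coding_codons)`.
#' @export
years_per_mutation <- function(clock) {
  1 / (clock$protein_coding_rate * clock$coding_sites)
}

#' @rdname years_per_mutation
#' @export
years_per_syn_mutation <- function(clock) {
  1 / (clock$synonymous_rate * clock$coding_codons)
}

#' Selection-corrected node age from overall rho
#'
#' The observed overall rho of a young node under-represents the long-run
#' protein-coding mutation count because transient deleterious variants
#' inflate it relative to its equilibrium composition. The correction maps
#' rho to its synonymous-equivalent count `rho * s(rho)` via the fitted
#' Gompertz curve, rescales by the asymptote `a` back to a selection-free
#' total count `rho_corr = rho * s(rho) / a`, and converts to calendar years
#' with the protein-coding clock: `age = rho_corr / (rate * coding_sites)`.
#'
#' @param rho_total overall protein-coding rho (vectorised, >= 0).
#' @param gompertz a [fit_gompertz()] result.
#' @param clock a [clock_config()].
#' @return ages in years.
#' @export
corrected_age <- function(rho_total, gompertz, clock) {
  if (any(rho_total < 0)) stop("rho_total must be >= 0")
  s <- predict_syn_proportion(gompertz, rho_total)
  rho_corr <- rho_total * s / gompertz$a
  rho_corr * years_per_mutation(clock)
}

#' Node age from synonymous rho
#'
#' Synonymous variants are taken as effectively neutral, so synonymous rho
#' accumulates linearly in time and dates a node directly:
#' `age = rho_syn / (synonymous_rate * coding_codons)`.
#'
#' @param rho_syn synonymous-only rho (vectorised, >= 0).
#' @param clock a [clock_config()].
#' @return ages in years.
#' @export
synonymous_age <- function(rho_syn, clock) {
  if (any(rho_syn < 0)) stop("rho_syn must be >= 0")
  rho_syn * years_per_syn_mutation(clock)
}

#' Correction-validation surface over seeded synthetic replicates
#'
#' Runs the full correction pipeline on a series of seeded synthetic
#' datasets: simulate tree and mutations, compute rho, agglomerate,
#' fit the Gompertz curve, then compare selection-corrected protein-coding
#' ages with synonymous ages via [validate_correction()]. The synonymous
#' clock is the generator's synonymous rate; the protein-coding clock is
#' the long-run total rate implied by the fitted equilibrium synonymous
#' fraction (`syn_rate / a`).
#'
#' @param seeds integer vector of replicate seeds.
#' @param n_tips,sigma generator settings passed to [simulation_config()]
#'   (defaults 63 and 3).
#' @param nu agglomeration variance threshold (default 2.5e-3).
#' @param ... further arguments for [simulation_config()].
#' @return data frame with one row per seed: `seed`, `pearson_r`, `slope`,
#'   `n_nodes`, `gompertz_a`.
#' @export
correction_validation_surface <- function(seeds, n_tips = 63L, sigma = 3,
                                          nu = 2.5e-3, ...) {
  out <- lapply(seeds, function(seed) {
    cfg <- simulation_config(n_tips = n_tips, sigma = sigma, seed = seed,
                             ...)
    ds <- simulate_dataset(cfg)
    rho <- rho_table(ds$tree)
    gfit <- fit_gompertz(agglomerate_nodes(node_points(rho), nu = nu))
    clock <- clock_config(
      protein_coding_rate = cfg$syn_rate_per_year / gfit$a,
      synonymous_rate = cfg$syn_rate_per_year,
      coding_sites = 1, coding_codons = 1, species = "synthetic")
    val <- validate_correction(rho, gfit, clock)
    data.frame(seed = seed, pearson_r = val$pearson_r, slope = val$slope,
               n_nodes = val$n_nodes, gompertz_a = gfit$a)
  })
  do.call(rbind, out)
}

#' Validate the selection correction against the synonymous clock
#'
#' For every internal node with synonymous rho above zero, computes the
#' selection-corrected protein-coding age and the synonymous age, then
#' summarises their agreement by the Pearson correlation and the
#' least-squares slope of corrected age on synonymous age through the
#' origin. An efficient correction yields correlation near 1 and slope
#' near 1.
#'
#' @param rho rho table from [rho_table()].
#' @param gompertz a [fit_gompertz()] result.
#' @param clock a [clock_config()].
#' @param min_nodes minimum number of usable internal nodes (default 10).
#' @return list with `pearson_r`, `slope`, `n_nodes`, and the per-node `ages`
#'   data frame (`synonymous_age`, `corrected_age`).
#' @export
validate_correction <- function(rho, gompertz, clock, min_nodes = 10L) {
  keep <- rho$n_tips > 1L & rho$rho_syn > 0
  if (sum(keep) < min_nodes)
    stop("need at least ", min_nodes, " internal nodes with rho_syn > 0, ",
         "found ", sum(keep))
  syn_age <- synonymous_age(rho$rho_syn[keep], clock)
  corr_age <- corrected_age(rho$rho_total[keep], gompertz, clock)
  list(pearson_r = cor(syn_age, corr_age),
       slope = sum(syn_age * corr_age) / sum(syn_age^2),
       n_nodes = sum(keep),
       ages = data.frame(label = rho$label[keep],
                         synonymous_age = syn_age,
                         corrected_age = corr_age,
                         stringsAsFactors = FALSE))
}
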