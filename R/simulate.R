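#' Simulation configuration
#'
#' Parameters of the synthetic data generator. Time is measured in abstract
#' "years"; the defaults use a rescaled unit in which the tree depth is 1,
#' so rates are totals per genome per tree depth. Defaults: a 63-tip
#' coalescent tree; synonymous mutations at 20 events per genome per unit
#' time (neutral, always retained); nonsynonymous attempts at 13 per genome
#' per unit time, giving a pre-selection synonymous fraction of
#' 20/33 = 0.606; attempt pathogenicity scores from Beta(1.8, 1), a
#' right-skewed distribution on \[0, 1\] with mean 0.643 and mass
#' concentrated at high scores, emulating the catalogue of all possible
#' amino-acid changes; and selection intensity `sigma = 3` per unit score
#' per year.
#'
#' A nonsynonymous attempt with score `g` arising at time-depth `tau`
#' (years before the present, measured at its branch midpoint) is retained
#' with probability `exp(-sigma * g * tau)`: deleterious variants are
#' progressively purged from older branches while synonymous variation
#' accumulates clock-like. This retention-thinning scheme keeps the tree
#' fixed and reproduces the observable signatures of lineage purging (the
#' score-depth gradient and the rise of the synonymous proportion with rho).
#'
#' @param n_tips number of tips (>= 2).
#' @param tree_model `"coalescent"` or `"yule"`.
#' @param syn_rate_per_year synonymous events per genome per year.
#' @param nonsyn_attempt_rate_per_year nonsynonymous attempts per genome per
#'   year.
#' @param score_shape1,score_shape2 Beta parameters of the attempt score
#'   distribution.
#' @param sigma selection intensity (per unit score per year, >= 0).
#' @param tree_depth_years root-to-tip depth the simulated tree is scaled
#'   to.
#' @param genome_positions virtual genome length used to draw event
#'   positions.
#' @param exact_times logical; thin events at their exact (uniform) time on
#'   the branch instead of the branch midpoint.
#' @param seed mandatory integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_tips = 63L,
                              tree_model = c("coalescent", "yule"),
                              syn_rate_per_year = 20,
                              nonsyn_attempt_rate_per_year = 13,
                              score_shape1 = 1.8, score_shape2 = 1.0,
                              sigma = 3, tree_depth_years = 1,
                              genome_positions = 11400L,
                              exact_times = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  tree_model <- match.arg(tree_model)
  stopifnot(n_tips >= 2L, syn_rate_per_year >= 0,
            nonsyn_attempt_rate_per_year >= 0, sigma >= 0,
            tree_depth_years > 0, score_shape1 > 0, score_shape2 > 0)
  structure(list(n_tips = as.integer(n_tips), tree_model = tree_model,
                 syn_rate_per_year = syn_rate_per_year,
                 nonsyn_attempt_rate_per_year = nonsyn_attempt_rate_per_year,
                 score_shape1 = score_shape1, score_shape2 = score_shape2,
                 sigma = sigma, tree_depth_years = tree_depth_years,
                 genome_positions = as.integer(genome_positions),
                 exact_times = isTRUE(exact_times),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Species-group simulation presets
#'
#' Tip counts mirroring six published mammalian intraspecific data sets.
#'
#' @return named integer vector of tip counts.
#' @export
species_tip_counts <- function() {
  c(bos = 280L, canis = 262L, mus = 77L, orcinus = 63L, pan = 55L,
    sus = 69L)
}

#' Simulate an ultrametric rooted tree
#'
#' Coalescent ([ape::rcoal()]) or Yule ([ape::rphylo()]) topology, rescaled
#' so the root-to-tip depth equals `tree_depth_years`. Reproducible given
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @return rooted ultrametric `phylo` with internal nodes named.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  phy <- switch(config$tree_model,
                coalescent = ape::rcoal(config$n_tips),
                yule = ape::rphylo(config$n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * config$tree_depth_years / depth
  prepare_tree(phy)
}

#' Simulate classified mutation events on a tree
#'
#' Synonymous events are Poisson on each branch at the synonymous rate and
#' always retained. Nonsynonymous candidates are Poisson at the attempt
#' rate; each draws a score from the Beta score distribution and is
#' retained with probability `exp(-sigma * g * tau)`, `tau` being the years
#' from the branch midpoint (or the exact event time when
#' `exact_times = TRUE`) to the present.
#'
#' @param phy rooted ultrametric `phylo` (e.g. from [simulate_tree()]).
#' @param config a [simulation_config()].
#' @return list of class `synthetic_dataset` with elements `tree` (an
#'   [annotated_tree()]), `truth` (generator parameters plus per-class event
#'   counts and attempt bookkeeping: attempt scores and retention flags).
#' @export
simulate_mutations <- function(phy, config) {
  set.seed(config$seed + 500009L)
  phy <- prepare_tree(phy)
  labels <- c(phy$tip.label, phy$node.label)
  depths <- ape::node.depth.edgelength(phy)  # years from root
  present <- max(depths)
  edge <- phy$edge
  elen <- phy$edge.length
  rows <- list()
  attempts <- list()
  for (e in seq_len(nrow(edge))) {
    ch <- edge[e, 2]
    len <- elen[e]
    t_child <- depths[ch]
    n_syn <- rpois(1L, config$syn_rate_per_year * len)
    if (n_syn > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        node = labels[ch], position = sample.int(config$genome_positions,
                                                 n_syn, replace = TRUE),
        from = NA_character_, to = NA_character_, class = "synonymous",
        score = NA_real_, stringsAsFactors = FALSE)
    n_att <- rpois(1L, config$nonsyn_attempt_rate_per_year * len)
    if (n_att > 0L) {
      g <- rbeta(n_att, config$score_shape1, config$score_shape2)
      tau <- if (config$exact_times) {
        present - (t_child - runif(n_att, 0, len))
      } else {
        rep(present - (t_child - len / 2), n_att)
      }
      keep <- runif(n_att) < exp(-config$sigma * g * tau)
      attempts[[length(attempts) + 1L]] <- data.frame(
        node = labels[ch], score = g, tau = tau, retained = keep,
        stringsAsFactors = FALSE)
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          node = labels[ch],
          position = sample.int(config$genome_positions, sum(keep),
                                replace = TRUE),
          from = NA_character_, to = NA_character_, class = "nonsynonymous",
          score = g[keep], stringsAsFactors = FALSE)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(), position = integer(),
               from = character(), to = character(), class = character(),
               score = numeric(), stringsAsFactors = FALSE)
  tree <- annotated_tree(phy, events)
  attempts <- if (length(attempts)) do.call(rbind, attempts) else
    data.frame(node = character(), score = numeric(), tau = numeric(),
               retained = logical(), stringsAsFactors = FALSE)
  structure(list(tree = tree,
                 truth = list(config = config,
                              n_synonymous = sum(events$class ==
                                                   "synonymous"),
                              n_nonsynonymous = sum(events$class ==
                                                      "nonsynonymous"),
                              n_attempts = nrow(attempts),
                              attempts = attempts,
                              total_branch_length = sum(elen),
                              expected_root_syn_fraction =
                                expected_root_syn_fraction(phy, config))),
            class = "synthetic_dataset")
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [simulate_tree()] followed by
#' [simulate_mutations()].
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_dataset` (see [simulate_mutations()]).
#' @export
simulate_dataset <- function(config) {
  phy <- simulate_tree(config)
  simulate_mutations(phy, config)
}

#' Expected synonymous fraction at the root of a given tree
#'
#' Exact generator expectation of the root's synonymous rho proportion for
#' a concrete tree, under the configured thinning scheme: tip-weighted sums
#' over branches of synonymous intensity versus retained nonsynonymous
#' intensity, with the retention probability `E_g[exp(-sigma g tau)]`
#' evaluated at the branch midpoint (default) or integrated along the
#' branch (`exact_times = TRUE`). This is the reference value for
#' parameter-recovery checks of the fitted synonymous-proportion curve
#' within the observed rho range.
#'
#' @param phy rooted ultrametric `phylo`.
#' @param config a [simulation_config()].
#' @return expected synonymous fraction in (0, 1\].
#' @export
expected_root_syn_fraction <- function(phy, config) {
  mu_s <- config$syn_rate_per_year
  mu_n <- config$nonsyn_attempt_rate_per_year
  if (mu_n == 0) return(1)
  r_mean <- function(tau) {
    vapply(tau, function(tt) {
      integrate(function(g)
        dbeta(g, config$score_shape1, config$score_shape2) *
          exp(-config$sigma * g * tt), 0, 1)$value
    }, numeric(1))
  }
  depths <- ape::node.depth.edgelength(phy)
  present <- max(depths)
  ntip <- ape::Ntip(phy)
  n_under <- node_tip_counts(phy)
  syn <- nonsyn <- 0
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    len <- phy$edge.length[e]
    if (len <= 0) next
    w <- n_under[ch] / ntip
    syn <- syn + w * mu_s * len
    retained <- if (config$exact_times) {
      integrate(function(u) r_mean(present - (depths[ch] - u)), 0,
                len)$value
    } else {
      len * r_mean(present - (depths[ch] - len / 2))
    }
    nonsyn <- nonsyn + w * mu_n * retained
  }
  syn / (syn + nonsyn)
}

node_tip_counts <- function(phy) {
  ntip <- ape::Ntip(phy)
  n <- c(rep(1L, ntip), integer(phy$Nnode))
  po <- postorder_nodes(phy)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  for (v in po[po > ntip]) n[v] <- sum(n[children[[as.character(v)]]])
  n
}

#' Generator-implied synonymous fraction at a given depth
#'
#' Expected synonymous proportion of the mutations retained along a lineage
#' of age `t`: `mu_s t / (mu_s t + mu_n integral_0^t r(tau) dtau)` with
#' `r(tau) = E[exp(-sigma g tau)]` over the Beta score distribution. At
#' `t = tree_depth_years` this is the generator's implied equilibrium
#' synonymous fraction against which a fitted Gompertz asymptote can be
#' checked.
#'
#' @param config a [simulation_config()].
#' @param t lineage age in years (default the tree depth).
#' @return synonymous fraction in (0, 1\].
#' @export
implied_syn_fraction <- function(config, t = config$tree_depth_years) {
  mu_s <- config$syn_rate_per_year
  mu_n <- config$nonsyn_attempt_rate_per_year
  if (mu_n == 0) return(1)
  r_tau <- function(tau) {
    vapply(tau, function(tt) {
      integrate(function(g)
        stats::dbeta(g, config$score_shape1, config$score_shape2) *
          exp(-config$sigma * g * tt), 0, 1)$value
    }, numeric(1))
  }
  retained <- integrate(r_tau, 0, t)$value
  (mu_s * t) / (mu_s * t + mu_n * retained)
}

#' Build a toy annotated reference genome
#'
#' Random protein-coding genes under the vertebrate mitochondrial code:
#' each gene starts with ATG/ATA, has stop-free internal codons and a
#' terminal stop (TAA/TAG/AGA/AGG). Optionally one gene is placed on the
#' minus strand (stored as its reverse complement, exercising ND6-style
#' handling) and one extra frame-shifted annotation is overlaid on the
#' first gene so that positions with two consequences exist (the
#' overlapping annotation is a reading-frame window, not an independent
#' start/stop-valid gene, mirroring out-of-frame mtDNA overlaps).
#'
#' @param n_genes number of genes (>= 1).
#' @param gene_lengths integer vector (recycled) of gene lengths in bp,
#'   each divisible by 3 and >= 9.
#' @param seed integer seed.
#' @param minus_strand logical; place the last gene on the minus strand.
#' @param overlap logical; add a frame-shifted overlapping annotation.
#' @param spacer bp of noncoding sequence between genes (default 4).
#' @return a [reference_genome()].
#' @export
make_toy_reference <- function(n_genes = 2L, gene_lengths = 30L, seed,
                               minus_strand = FALSE, overlap = FALSE,
                               spacer = 4L) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  gene_lengths <- rep_len(as.integer(gene_lengths), n_genes)
  if (any(gene_lengths %% 3L != 0L | gene_lengths < 9L))
    stop("gene lengths must be multiples of 3 and >= 9")
  code <- mito_genetic_code()
  stops <- names(code)[code == "*"]
  internal_pool <- setdiff(names(code), stops)
  random_cds <- function(len) {
    n_codon <- len %/% 3L
    paste0(sample(c("ATG", "ATA"), 1L),
           paste(sample(internal_pool, n_codon - 2L, replace = TRUE),
                 collapse = ""),
           sample(c("TAA", "TAG", "AGA", "AGG"), 1L))
  }
  seq_parts <- character(0)
  genes <- list()
  pos <- 1L
  for (i in seq_len(n_genes)) {
    cds <- random_cds(gene_lengths[i])
    on_minus <- minus_strand && i == n_genes
    seq_parts <- c(seq_parts, if (on_minus) revcomp(cds) else cds)
    genes[[i]] <- data.frame(
      gene = paste0("G", i), start = pos,
      end = pos + gene_lengths[i] - 1L,
      strand = if (on_minus) "-" else "+", codon_start = 0L,
      incomplete_stop = FALSE, stringsAsFactors = FALSE)
    pos <- pos + gene_lengths[i]
    if (spacer > 0L) {
      seq_parts <- c(seq_parts,
                     paste(sample(DNA_BASES, spacer, replace = TRUE),
                           collapse = ""))
      pos <- pos + spacer
    }
  }
  if (overlap) {
    g1 <- genes[[1]]
    ov_len <- ((g1$end - g1$start - 3L) %/% 3L) * 3L
    genes[[length(genes) + 1L]] <- data.frame(
      gene = "G1ov", start = g1$start + 1L,
      end = g1$start + ov_len, strand = "+", codon_start = 0L,
      incomplete_stop = FALSE, stringsAsFactors = FALSE)
  }
  reference_genome("toy", paste(seq_parts, collapse = ""),
                   do.call(rbind, genes))
}
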