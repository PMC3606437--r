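# Independent oracles used across tests. These deliberately avoid the
# package's incremental code paths: classification is checked by rebuilding
# the whole mutated genome and translating complete genes with Biostrings;
# rho by direct tip-path counting; parsimony by exhaustive enumeration of
# ancestral states.

toy_atggcc <- function() {
  reference_genome("toy", "ATGGCCTAA",
                   data.frame(gene = "g1", start = 1, end = 9,
                              strand = "+", codon_start = 0,
                              incomplete_stop = FALSE))
}

# Full-translation classification oracle: one row (gene, class) per gene.
oracle_classify <- function(genome, position, alt) {
  mutated <- genome$sequence
  substring(mutated, position, position) <- alt
  code <- Biostrings::getGeneticCode("2")
  out <- list()
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    span <- if (g$start > g$end) c(g$start:genome$length, 1:g$end)
            else g$start:g$end
    get_cds <- function(seqstr) {
      bases <- strsplit(seqstr, "")[[1]][span]
      cds <- paste(bases, collapse = "")
      if (g$strand == "-")
        cds <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      if (g$codon_start > 0) cds <- substring(cds, g$codon_start + 1)
      nc <- nchar(cds)
      substring(cds, 1, nc - nc %% 3)
    }
    ref_cds <- get_cds(genome$sequence)
    alt_cds <- get_cds(mutated)
    if (ref_cds == alt_cds) next  # position outside this gene's frame
    tr <- function(cds) strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), genetic.code = code,
      no.init.codon = TRUE, if.fuzzy.codon = "X")), "")[[1]]
    p_ref <- tr(ref_cds)
    p_alt <- tr(alt_cds)
    diff_idx <- which(p_ref != p_alt)
    cl <- if (length(diff_idx) == 0) {
      # same protein: synonymous, or a stop replaced by another stop
      changed_codon <- ceiling(which(strsplit(ref_cds, "")[[1]] !=
                                       strsplit(alt_cds, "")[[1]]) / 3)
      if (p_ref[changed_codon] == "*") "stop_retained" else "synonymous"
    } else {
      ra <- p_ref[diff_idx[1]]
      aa <- p_alt[diff_idx[1]]
      if (aa == "*") "stop_gain" else if (ra == "*") "stop_loss"
      else "nonsynonymous"
    }
    out[[length(out) + 1]] <- data.frame(gene = g$gene, class = cl,
                                         stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(gene = NA_character_,
                                      class = "noncoding",
                                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Direct definition of rho: mean number of filter-passing events on the
# node-to-tip paths.
oracle_rho <- function(tree, keep_classes) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  ev <- tree$events
  m_edge <- tabulate(ev$node_id[ev$class %in% keep_classes], nbins = nnode)
  parent <- integer(nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  # events on the path from node v down to tip t
  path_count <- function(v, t) {
    cnt <- 0
    while (t != v) {
      cnt <- cnt + m_edge[t]
      t <- parent[t]
    }
    cnt
  }
  tips_under <- function(v) {
    if (v <= ntip) return(v)
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_under))
  }
  vapply(seq_len(nnode), function(v) {
    tips <- tips_under(v)
    mean(vapply(tips, function(t) path_count(v, t), numeric(1)))
  }, numeric(1))
}

# Exhaustive-minimum parsimony cost for one site on a rooted tree.
oracle_parsimony_cost <- function(phy, tip_states, root_state = NULL) {
  ntip <- ape::Ntip(phy)
  nint <- phy$Nnode
  root <- ntip + 1L
  bases <- c("A", "C", "G", "T")
  tip_states <- tip_states[phy$tip.label]
  grids <- rep(list(bases), nint)
  if (!is.null(root_state)) grids[[1]] <- root_state  # root is node ntip+1
  grid <- do.call(expand.grid,
                  c(grids, list(stringsAsFactors = FALSE)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- c(rep(NA_character_, ntip), unlist(grid[r, ]))
    assign[seq_len(ntip)] <- tip_states
    cost <- 0
    for (e in seq_len(nrow(phy$edge))) {
      a <- assign[phy$edge[e, 1]]
      b <- assign[phy$edge[e, 2]]
      if (!is.na(b) && b %in% bases && a != b) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

# Closed-form Welch t statistic and Satterthwaite df.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

random_annotated_tree <- function(n_tips, seed, syn_lambda = 0.8,
                                  nonsyn_lambda = 0.5) {
  set.seed(seed)
  phy <- ape::rtree(n_tips)
  phy$node.label <- NULL
  tree0 <- annotated_tree(phy, data.frame(node = character(),
                                          position = integer(),
                                          from = character(),
                                          to = character(),
                                          class = character(),
                                          score = numeric()))
  labels <- c(tree0$phy$tip.label, tree0$phy$node.label)
  root <- ape::Ntip(tree0$phy) + 1L
  ev <- list()
  for (ch in setdiff(seq_along(labels), root)) {
    for (cl in c("synonymous", "nonsynonymous", "other")) {
      lam <- switch(cl, synonymous = syn_lambda,
                    nonsynonymous = nonsyn_lambda, other = 0.2)
      n <- rpois(1, lam)
      if (n > 0)
        ev[[length(ev) + 1]] <- data.frame(
          node = labels[ch], position = sample.int(1000, n, replace = TRUE),
          from = "A", to = "G", class = cl, score = NA_real_,
          stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(node = character(), position = integer(),
               from = character(), to = character(), class = character(),
               score = numeric())
  annotated_tree(tree0$phy, events)
}
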