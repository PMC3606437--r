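#' Per-node rho depth statistics
#'
#' The rho statistic of a node is the mean number of mutation events
#' separating the node from its descendant tips (averaged over tips), a
#' unit-free proxy for node age. It is computed in two variants: overall
#' protein-coding rho (synonymous plus nonsynonymous events) and
#' synonymous-only rho. Events of class `other` (stop-affecting, noncoding)
#' enter neither variant. Tips have rho = 0.
#'
#' Internally the tip-weighted recursion
#' \deqn{\rho(v) = \sum_c n_c\,(\rho(c) + m_{v\to c}) / \sum_c n_c}
#' is used, where the sum runs over the children of `v`, `n_c` is the number
#' of tips under child `c` and `m` the number of filter-passing events on the
#' connecting branch; this is algebraically identical to the direct
#' tip-path-count mean.
#'
#' @param tree an [annotated_tree()].
#' @param filter `"protein_coding_all"` or `"synonymous_only"`.
#' @return `compute_rho()`: data frame with columns `node_id`, `label`,
#'   `n_tips`, `rho`. `rho_table()`: the two variants joined, with columns
#'   `node_id`, `label`, `n_tips`, `rho_total`, `rho_syn`.
#' @export
compute_rho <- function(tree, filter = c("protein_coding_all",
                                         "synonymous_only")) {
  filter <- match.arg(filter)
  keep <- if (filter == "synonymous_only") "synonymous"
          else c("synonymous", "nonsynonymous")
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  ev <- tree$events
  m_edge <- tabulate(ev$node_id[ev$class %in% keep], nbins = nnode)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  n_tips <- c(rep(1L, ntip), integer(phy$Nnode))
  rho <- numeric(nnode)
  po_nodes <- postorder_nodes(phy)
  # internal nodes in post-order: every child is final before its parent
  for (v in po_nodes[po_nodes > ntip]) {
    kids <- children[[as.character(v)]]
    n_tips[v] <- sum(n_tips[kids])
    rho[v] <- sum(n_tips[kids] * (rho[kids] + m_edge[kids])) / n_tips[v]
  }
  labels <- c(phy$tip.label, phy$node.label)
  data.frame(node_id = seq_len(nnode), label = labels, n_tips = n_tips,
             rho = rho, stringsAsFactors = FALSE)
}

#' @rdname compute_rho
#' @export
rho_table <- function(tree) {
  tot <- compute_rho(tree, "protein_coding_all")
  syn <- compute_rho(tree, "synonymous_only")
  data.frame(tot[, c("node_id", "label", "n_tips")],
             rho_total = tot$rho, rho_syn = syn$rho,
             stringsAsFactors = FALSE)
}

#' Per-occurrence variant observations with lower-node rho
#'
#' Tags every protein-coding mutation event (synonymous or nonsynonymous)
#' with the overall and synonymous rho of the lower (child-side) node of its
#' branch. The lower node's rho is a lower bound on the depth of the
#' mutation in the tree. Recurrent mutations appear once per independent
#' origin.
#'
#' @param tree an [annotated_tree()].
#' @param rho rho table from [rho_table()] (recomputed when omitted).
#' @return data frame with columns `occurrence_id`, `node`, `position`,
#'   `class`, `score`, `rho_total_lower`, `rho_syn_lower`.
#' @export
observations <- function(tree, rho = rho_table(tree)) {
  ev <- tree$events
  ev <- ev[ev$class %in% c("synonymous", "nonsynonymous"), , drop = FALSE]
  data.frame(occurrence_id = ev$occurrence_id, node = ev$node,
             position = ev$position, class = ev$class, score = ev$score,
             rho_total_lower = rho$rho_total[ev$node_id],
             rho_syn_lower = rho$rho_syn[ev$node_id],
             stringsAsFactors = FALSE)
}
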