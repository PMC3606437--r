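#' Map mutations onto branches by Fitch parsimony
#'
#' Assigns, per alignment column, a most-parsimonious set of state changes to
#' the branches of a rooted tree (Fitch up-pass followed by a top-down final
#' pass). Ambiguity in the final pass is resolved deterministically: a child
#' keeps the parent's state whenever its preliminary state set allows it
#' (delaying changes toward the tips), otherwise the alphabetically smallest
#' allowed base is taken. Every inferred change is classified against the
#' reference genome; independent origins of the same change (homoplasies)
#' receive distinct occurrence ids.
#'
#' Gaps and ambiguity codes in tip sequences are treated as missing data
#' (compatible with every base) and never generate events of their own.
#'
#' @param phy rooted `ape::phylo`; tip labels must match `tip_sequences`
#'   names.
#' @param tip_sequences named character vector of equal-length aligned
#'   sequences (or a `Biostrings::DNAStringSet`).
#' @param genome optional [reference_genome()] used to classify changes;
#'   without it every event has class `other`.
#' @param ancestor optional ancestral/outgroup sequence fixing the root
#'   state per site; defaults to the Fitch root set with a lexicographic
#'   tie-break.
#' @return An [annotated_tree()] whose events carry `site` = `position`.
#' @export
map_mutations_parsimony <- function(phy, tip_sequences, genome = NULL,
                                    ancestor = NULL) {
  if (inherits(tip_sequences, "DNAStringSet"))
    tip_sequences <- setNames(as.character(tip_sequences),
                              names(tip_sequences))
  phy <- prepare_tree(phy)
  ntip <- ape::Ntip(phy)
  missing_tips <- setdiff(phy$tip.label, names(tip_sequences))
  if (length(missing_tips)) stop("no sequence for tip(s): ",
                                 paste(missing_tips, collapse = ", "))
  tip_sequences <- toupper(tip_sequences[phy$tip.label])
  lens <- unique(nchar(tip_sequences))
  if (length(lens) != 1L) stop("tip sequences have unequal lengths")
  if (!is.null(ancestor)) {
    ancestor <- toupper(ancestor)
    if (nchar(ancestor) != lens) stop("ancestor length mismatch")
  }
  L <- lens
  tipmat <- do.call(rbind, strsplit(tip_sequences, "", fixed = TRUE))

  po_edges <- ape::reorder.phylo(phy, "postorder")$edge
  root <- ntip + 1L
  nnode <- ntip + phy$Nnode
  children <- split(po_edges[, 2], po_edges[, 1])
  # internal nodes in post-order (children strictly before parents)
  po_nodes <- postorder_nodes(phy)
  internal_po <- po_nodes[po_nodes > ntip]

  events <- list()
  for (site in seq_len(L)) {
    col <- tipmat[, site]
    known <- col %in% DNA_BASES
    if (length(unique(col[known])) <= 1L &&
        (is.null(ancestor) ||
         !substring(ancestor, site, site) %in% DNA_BASES ||
         all(col[known] == substring(ancestor, site, site))))
      next  # invariant site (relative to the root state): no events
    # state sets as logical 4-vectors
    sets <- matrix(FALSE, nrow = nnode, ncol = 4L)
    sets[cbind(which(known), match(col[known], DNA_BASES))] <- TRUE
    sets[which(!known), ] <- TRUE  # missing data: compatible with any base
    for (v in internal_po) {
      kids <- children[[as.character(v)]]
      s <- sets[kids[1], ]
      for (k in kids[-1]) {
        inter <- s & sets[k, ]
        s <- if (any(inter)) inter else s | sets[k, ]
      }
      sets[v, ] <- s
    }
    final <- character(nnode)
    root_base <- if (!is.null(ancestor)) substring(ancestor, site, site)
                 else NA_character_
    if (!is.na(root_base) && root_base %in% DNA_BASES) {
      final[root] <- root_base
    } else {
      final[root] <- DNA_BASES[which(sets[root, ])[1]]
    }
    # pre-order final pass
    for (e in rev(seq_len(nrow(po_edges)))) {
      par <- po_edges[e, 1]; ch <- po_edges[e, 2]
      if (ch <= ntip) {
        final[ch] <- if (known[ch]) col[ch] else final[par]
      } else {
        pset <- sets[ch, ]
        final[ch] <- if (pset[match(final[par], DNA_BASES)]) final[par]
                     else DNA_BASES[which(pset)[1]]
      }
      if (final[ch] != final[par]) {
        events[[length(events) + 1L]] <- data.frame(
          node_id = ch, position = site, from = final[par], to = final[ch],
          stringsAsFactors = FALSE)
      }
    }
  }
  labels <- c(phy$tip.label, phy$node.label)
  if (length(events)) {
    ev <- do.call(rbind, events)
    ev$node <- labels[ev$node_id]
    ev$class <- if (is.null(genome)) "other" else
      vapply(seq_len(nrow(ev)), function(i) {
        cons <- classify_change(genome, ev$position[i], ev$from[i], ev$to[i])
        resolve_consequence_classes(cons$class)
      }, character(1))
    ev$score <- NA_real_
    ev <- ev[order(ev$position, ev$node_id),
             c("node", "position", "from", "to", "class", "score")]
  } else {
    ev <- data.frame(node = character(), position = integer(),
                     from = character(), to = character(),
                     class = character(), score = numeric(),
                     stringsAsFactors = FALSE)
  }
  annotated_tree(phy, ev)
}

#' Load an aligned FASTA as named sequences
#'
#' @param path path to an aligned FASTA file.
#' @return named character vector of sequences.
#' @export
load_alignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}
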