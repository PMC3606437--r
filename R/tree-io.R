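#' Construct an annotated tree
#'
#' Binds a rooted `phylo` topology to a table of mutation events placed on
#' its branches. Each event is attached to the branch above the named child
#' node; recurrent mutations at the same site carry distinct
#' `occurrence_id`s, so homoplasies enter downstream statistics once per
#' independent origin.
#'
#' @param phy rooted `ape::phylo` object. Internal nodes without labels are
#'   auto-named `N1..Nk` in post-order.
#' @param events data frame with columns `node` (label of the branch's child
#'   node), `position`, `from`, `to`, `class` (one of `synonymous`,
#'   `nonsynonymous`, `other`) and optionally `score`.
#' @return An object of class `annotated_tree` with elements `phy`, `events`
#'   (with added integer `node_id` and `occurrence_id`), `node_ids` (label ->
#'   ape node number).
#' @export
annotated_tree <- function(phy, events) {
  phy <- prepare_tree(phy)
  ids <- node_id_map(phy)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (!nrow(events)) {
    events <- data.frame(node = character(), position = integer(),
                         from = character(), to = character(),
                         class = character(), score = numeric(),
                         stringsAsFactors = FALSE)
  }
  need <- c("node", "position", "from", "to", "class")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events lack column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(events$score)) events$score <- NA_real_
  unknown <- setdiff(unique(events$node), names(ids))
  if (length(unknown)) stop("event node label(s) not in tree: ",
                            paste(unknown, collapse = ", "))
  root <- ape::Ntip(phy) + 1L
  events$node_id <- unname(ids[events$node])
  if (any(events$node_id == root))
    stop("events cannot be placed above the root node")
  bad <- setdiff(unique(events$class),
                 c("synonymous", "nonsynonymous", "other"))
  if (length(bad)) stop("unknown event class(es): ",
                        paste(bad, collapse = ", "))
  events$occurrence_id <- seq_len(nrow(events))
  structure(list(phy = phy, events = events, node_ids = ids),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("annotated_tree: ", ape::Ntip(x$phy), " tips, ",
      nrow(x$events), " mutation events (",
      sum(x$events$class == "synonymous"), " synonymous, ",
      sum(x$events$class == "nonsynonymous"), " nonsynonymous)\n", sep = "")
  invisible(x)
}

# Ensure rooted topology with unique node labels; unlabeled internal nodes
# get names N1..Nk in post-order (tip-ward nodes first, root last).
prepare_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' object")
  # structural rootedness: exactly one node without a parent (a basal
  # polytomy is accepted and read as a star radiating from the ancestor)
  parentless <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(parentless) != 1L) stop("tree must have exactly one root")
  n_int <- phy$Nnode
  if (is.null(phy$node.label) || all(is.na(phy$node.label)) ||
      all(phy$node.label == "")) {
    po <- postorder_nodes(phy)
    internal_po <- po[po > ape::Ntip(phy)]
    lab <- character(n_int)
    lab[internal_po - ape::Ntip(phy)] <- paste0("N", seq_along(internal_po))
    phy$node.label <- lab
  }
  labs <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labs)) stop("tree node labels are not unique")
  phy
}

node_id_map <- function(phy) {
  setNames(seq_len(ape::Ntip(phy) + phy$Nnode),
           c(phy$tip.label, phy$node.label))
}

# Node numbers in post-order (children strictly before parents).
postorder_nodes <- function(phy) {
  root <- ape::Ntip(phy) + 1L
  children <- split(phy$edge[, 2], phy$edge[, 1])
  s1 <- root
  s2 <- integer(0)
  while (length(s1)) {
    v <- s1[length(s1)]
    s1 <- s1[-length(s1)]
    s2 <- c(s2, v)
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) s1 <- c(s1, kids)
  }
  rev(s2)
}

#' Load a tree with pre-annotated branch mutations
#'
#' Reads a rooted Newick tree and a TSV of branch mutations (columns
#' `node`, `position`, `from`, `to`, optionally `class` and `score`). When a
#' reference genome is supplied, missing classes are filled by
#' [classify_substitution()] (resolved across covering genes) and, under
#' `strict = TRUE`, supplied classes that contradict the reference
#' classification raise an error.
#'
#' @param newick_path path to a rooted Newick file.
#' @param events_path path to the branch-mutation TSV.
#' @param genome optional [reference_genome()] for class validation.
#' @param strict logical; error on class/reference disagreement.
#' @return An [annotated_tree()].
#' @export
load_annotated_tree <- function(newick_path, events_path, genome = NULL,
                                strict = FALSE) {
  phy <- ape::read.tree(newick_path)
  if (is.null(phy)) stop("could not parse Newick file: ", newick_path)
  events <- read.delim(events_path, stringsAsFactors = FALSE)
  if (is.null(events$class)) events$class <- NA_character_
  if (!is.null(genome)) {
    for (i in seq_len(nrow(events))) {
      cons <- classify_change(genome, events$position[i],
                              events$from[i], events$to[i])
      resolved <- resolve_consequence_classes(cons$class)
      if (is.na(events$class[i])) {
        events$class[i] <- resolved
      } else if (strict && events$class[i] != resolved) {
        stop("class mismatch at position ", events$position[i],
             ": given '", events$class[i], "', reference implies '",
             resolved, "'")
      }
    }
  }
  if (anyNA(events$class))
    stop("event class missing and no reference genome supplied")
  annotated_tree(phy, events)
}

resolve_consequence_classes <- function(cl) {
  if (any(cl == "nonsynonymous")) "nonsynonymous"
  else if (length(cl) && all(cl == "synonymous")) "synonymous"
  else "other"
}

#' Write branch mutation events to TSV
#'
#' @param tree an [annotated_tree()].
#' @param path output path.
#' @return invisibly, the written data frame.
#' @export
write_events_tsv <- function(tree, path) {
  ev <- tree$events[, c("node", "position", "from", "to", "class", "score",
                        "occurrence_id")]
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}
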