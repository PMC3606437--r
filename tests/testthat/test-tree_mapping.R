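test_that("annotated trees load from Newick plus branch-mutation TSV", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)X:1,C:2)R;", nwk)
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(node = c("A", "X"), position = c(5, 9),
                         from = c("A", "C"), to = c("G", "T"),
                         class = c("synonymous", "nonsynonymous")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- load_annotated_tree(nwk, tsv)
  expect_s3_class(tr, "annotated_tree")
  expect_equal(nrow(tr$events), 2)
  expect_equal(sort(tr$events$occurrence_id), 1:2)

  write.table(data.frame(node = "Z", position = 5, from = "A", to = "G",
                         class = "synonymous"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_annotated_tree(nwk, tsv), "not in tree")
})

test_that("reference validation of event classes works in strict mode", {
  g <- toy_atggcc()
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)X:1,C:2)R;", nwk)
  tsv <- tempfile(fileext = ".tsv")
  # position 3 G->A is synonymous (ATA = Met); claiming nonsynonymous lies
  write.table(data.frame(node = "A", position = 3, from = "G", to = "A",
                         class = "nonsynonymous"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_annotated_tree(nwk, tsv, genome = g, strict = TRUE),
               "mismatch at position 3")
  # without strict the supplied class is kept
  tr <- load_annotated_tree(nwk, tsv, genome = g, strict = FALSE)
  expect_equal(tr$events$class, "nonsynonymous")
  # missing classes are filled from the reference
  write.table(data.frame(node = "A", position = 3, from = "G", to = "A"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tr2 <- load_annotated_tree(nwk, tsv, genome = g)
  expect_equal(tr2$events$class, "synonymous")
})

test_that("parsimony places private, shared and homoplasic variants", {
  g <- toy_atggcc()
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ref <- g$sequence
  mutate_at <- function(s, position, base) {
    substring(s, position, position) <- base
    s
  }
  # one private variant per tip
  seqs <- c(A = mutate_at(ref, 3, "A"), B = mutate_at(ref, 6, "T"),
            C = mutate_at(ref, 4, "A"), D = mutate_at(ref, 5, "A"))
  tr <- map_mutations_parsimony(star, seqs, genome = g, ancestor = ref)
  expect_equal(nrow(tr$events), 4)
  expect_setequal(tr$events$node, c("A", "B", "C", "D"))

  # variant shared by the (A,B) clade maps to the internal branch
  bal <- ape::read.tree(text = "((A,B),(C,D));")
  seqs2 <- c(A = mutate_at(ref, 3, "A"), B = mutate_at(ref, 3, "A"),
             C = ref, D = ref)
  tr2 <- map_mutations_parsimony(bal, seqs2, genome = g, ancestor = ref)
  expect_equal(nrow(tr2$events), 1)
  expect_equal(tr2$events$from, "G")
  expect_equal(tr2$events$to, "A")
  expect_equal(tr2$events$class, "synonymous")
  ab_parent <- tr2$phy$node.label[
    tr2$phy$edge[match(match("A", tr2$phy$tip.label), tr2$phy$edge[, 2]), 1] -
      ape::Ntip(tr2$phy)]
  expect_equal(tr2$events$node, ab_parent)

  # homoplasy: same variant in A and C needs two independent events
  seqs3 <- c(A = mutate_at(ref, 6, "T"), B = ref,
             C = mutate_at(ref, 6, "T"), D = ref)
  tr3 <- map_mutations_parsimony(bal, seqs3, genome = g, ancestor = ref)
  expect_equal(nrow(tr3$events), 2)
  expect_setequal(tr3$events$node, c("A", "C"))
  expect_equal(length(unique(tr3$events$occurrence_id)), 2)
})

test_that("Fitch mapping attains the exhaustive-minimum parsimony score", {
  bases <- c("A", "C", "G", "T")
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    phy <- ape::rtree(n)
    phy$node.label <- NULL
    n_sites <- 6
    seqmat <- matrix(sample(bases, n * n_sites, replace = TRUE,
                            prob = c(0.4, 0.1, 0.4, 0.1)),
                     nrow = n)
    seqs <- setNames(apply(seqmat, 1, paste, collapse = ""), phy$tip.label)
    tr <- map_mutations_parsimony(phy, seqs)
    for (site in seq_len(n_sites)) {
      got <- sum(tr$events$position == site)
      want <- oracle_parsimony_cost(phy, setNames(seqmat[, site],
                                                  phy$tip.label))
      expect_equal(got, want, info = paste("seed", seed, "site", site))
    }
  }
})

test_that("a fixed ancestral state constrains the root assignment", {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  seqs <- c(A = "T", B = "T", C = "T", D = "T")
  # all tips differ from the declared ancestor: with the root held at A the
  # minimum is one change on each basal branch
  tr <- map_mutations_parsimony(phy, seqs, ancestor = "A")
  want <- oracle_parsimony_cost(phy, seqs, root_state = "A")
  expect_equal(nrow(tr$events), want)
  expect_equal(want, 2)
  expect_true(all(tr$events$from == "A" & tr$events$to == "T"))
})

test_that("mapping is invariant to tip-order permutation", {
  g <- toy_atggcc()
  ref <- g$sequence
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  seqs <- c(A = "ATAGCCTAA", B = "ATAGCCTAA", C = "ATGGCTTAA",
            D = "ATGGCCTAA")
  tr1 <- map_mutations_parsimony(phy, seqs, genome = g, ancestor = ref)
  tr2 <- map_mutations_parsimony(phy, rev(seqs), genome = g, ancestor = ref)
  key <- function(tr) sort(paste(tr$events$node, tr$events$position,
                                 tr$events$from, tr$events$to))
  expect_equal(key(tr1), key(tr2))
})

test_that("per-site mappings concatenate (site independence)", {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  s1 <- c(A = "T", B = "T", C = "A", D = "A")
  s2 <- c(A = "G", B = "C", C = "C", D = "C")
  both <- setNames(paste0(s1, s2[names(s1)]), names(s1))
  tr1 <- map_mutations_parsimony(phy, s1, ancestor = "A")
  tr2 <- map_mutations_parsimony(phy, s2, ancestor = "C")
  trb <- map_mutations_parsimony(phy, both, ancestor = "AC")
  key <- function(tr, shift = 0) sort(paste(tr$events$node,
                                            tr$events$position + shift,
                                            tr$events$from, tr$events$to))
  expect_equal(key(trb), sort(c(key(tr1), key(tr2, shift = 1))))
})

test_that("gaps and ambiguity codes are ignored as missing data", {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  seqs <- c(A = "T", B = "-", C = "N", D = "A")
  tr <- map_mutations_parsimony(phy, seqs, ancestor = "A")
  # only the unambiguous T in A demands a change; the missing tip B lends it
  # support, so the single event sits on the branch above the (A,B) clade
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$to, "T")
  expect_equal(nrow(tr$events),
               oracle_parsimony_cost(phy, seqs, root_state = "A"))
})
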