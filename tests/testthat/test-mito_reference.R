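test_that("load_reference accepts a minimal genome and validates spans", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">toy", "ATGGCCTAA"), fa)
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = "g1", start = 1, end = 9, strand = "+",
                         codon_start = 0),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- load_reference(fa, tsv)
  expect_s3_class(g, "mito_reference")
  expect_equal(g$length, 9)
  expect_equal(nrow(g$genes), 1)

  # span of 8 without the incomplete-stop flag is rejected
  write.table(data.frame(gene = "g1", start = 1, end = 8, strand = "+",
                         codon_start = 0),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_reference(fa, tsv), "multiple of 3")

  # but the flag makes the partial terminal codon legal
  write.table(data.frame(gene = "g1", start = 1, end = 8, strand = "+",
                         codon_start = 0, incomplete_stop = TRUE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(g8 <- load_reference(fa, tsv))
  # the partial codon is not classified: positions 7-8 are out of frame
  expect_equal(classify_substitution(g8, 8, "C")$class, "noncoding")

  # minus-strand annotation (ND6-style) is accepted
  write.table(data.frame(gene = "nd6", start = 1, end = 9, strand = "-",
                         codon_start = 0),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(load_reference(fa, tsv))

  expect_error(reference_genome("x", "ATGNCCTAA",
                                data.frame(gene = "g", start = 1, end = 9,
                                           strand = "+", codon_start = 0)),
               "non-ACGT")
  expect_silent(reference_genome("x", "ATGNCCTAA",
                                 data.frame(gene = "g", start = 1, end = 9,
                                            strand = "+", codon_start = 0),
                                 ambiguity = "mask"))
})

test_that("enumeration is complete, ordered and labels mutation types", {
  g <- toy_atggcc()
  v <- enumerate_all_substitutions(g)
  key <- paste(v$position, v$alt)
  expect_equal(length(unique(key)), 3 * g$length)
  expect_false(any(v$ref == v$alt))
  # per site: one transition, two transversions
  per_site <- tapply(v$type[!duplicated(key)],
                     v$position[!duplicated(key)],
                     function(x) sum(x == "transition"))
  expect_true(all(per_site == 1))
  # deterministic order: positions ascending, alts A<C<G<T within position
  expect_false(is.unsorted(v$position))
})

test_that("toy-gene classification matches the genetic code", {
  g <- toy_atggcc()
  v <- enumerate_all_substitutions(g)
  coding <- v[v$position <= 6, ]
  expect_equal(sum(coding$class == "synonymous"), 4)   # ATA, GCA/GCG/GCT
  expect_equal(sum(coding$class == "nonsynonymous"), 13)
  expect_equal(sum(coding$class == "stop_gain"), 1)    # ATG -> AGG
  agg <- coding[coding$class == "stop_gain", ]
  expect_equal(agg$position, 2)
  expect_equal(agg$alt, "G")

  # stop codon TAA: T->C gives CAA = Gln, a stop loss
  cons <- classify_substitution(g, 7, "C")
  expect_equal(cons$class, "stop_loss")
  expect_equal(cons$alt_aa, "Q")
  # ATA is Met in the vertebrate mitochondrial code
  expect_equal(classify_substitution(g, 3, "A")$class, "synonymous")
  # GCC -> GCT is Ala
  expect_equal(classify_substitution(g, 6, "T")$class, "synonymous")
  # TAA -> TAG stays a stop
  expect_equal(classify_substitution(g, 9, "G")$class, "stop_retained")

  expect_error(classify_substitution(g, 1, "A"), "alt equals")
  expect_error(classify_substitution(g, 10, "A"), "outside")
})

test_that("classification equals full-translation oracle on exhaustive toys", {
  genomes <- list(
    toy_atggcc(),
    make_toy_reference(n_genes = 2, gene_lengths = c(21, 15), seed = 11),
    make_toy_reference(n_genes = 2, gene_lengths = c(18, 24), seed = 12,
                       minus_strand = TRUE),
    make_toy_reference(n_genes = 1, gene_lengths = 30, seed = 13,
                       overlap = TRUE))
  for (g in genomes) {
    for (position in seq_len(g$length)) {
      ref <- substring(g$sequence, position, position)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- classify_substitution(g, position, alt)
        want <- oracle_classify(g, position, alt)
        got <- got[order(got$gene), ]
        want <- want[order(want$gene), ]
        expect_equal(got$class, want$class,
                     info = paste(g$name, position, ref, ">", alt))
      }
    }
  }
})

test_that("genes wrapping the circular origin classify correctly", {
  # gene spans positions 10..12 then 1..6 of a 12-bp circle: cds = ATGGCCTAA
  g <- reference_genome("wrap", "GCCTAAGGGATG",
                        data.frame(gene = "g1", start = 10, end = 6,
                                   strand = "+", codon_start = 0),
                        circular = TRUE)
  # position 3 is the 3rd codon base of codon 2 (GCC); C->T synonymous
  expect_equal(classify_substitution(g, 3, "T")$class, "synonymous")
  # position 10 is the A of ATG; A->G -> GTG (Val), nonsynonymous
  cons <- classify_substitution(g, 10, "G")
  expect_equal(cons$class, "nonsynonymous")
  expect_equal(cons$ref_aa, "M")
  # oracle agreement across the whole wrapped genome
  for (position in seq_len(g$length)) {
    ref <- substring(g$sequence, position, position)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      expect_equal(classify_substitution(g, position, alt)$class,
                   oracle_classify(g, position, alt)$class,
                   info = paste("wrap", position, alt))
    }
  }
})

test_that("minus-strand classification mirrors the reverse complement", {
  set.seed(41)
  cds <- paste0("ATG", "CATTGGCGA", "TAA")
  plus <- reference_genome("p", cds,
                           data.frame(gene = "g", start = 1, end = 15,
                                      strand = "+", codon_start = 0))
  minus_seq <- paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]),
                     collapse = "")
  minus <- reference_genome("m", minus_seq,
                            data.frame(gene = "g", start = 1, end = 15,
                                       strand = "-", codon_start = 0))
  L <- nchar(cds)
  for (position in seq_len(L)) {
    ref_p <- substring(cds, position, position)
    for (alt in setdiff(c("A", "C", "G", "T"), ref_p)) {
      mirrored_pos <- L - position + 1
      mirrored_alt <- chartr("ACGT", "TGCA", alt)
      expect_equal(
        classify_substitution(plus, position, alt)$class,
        classify_substitution(minus, mirrored_pos, mirrored_alt)$class,
        info = paste(position, alt))
    }
  }
})

test_that("nonsynonymous catalogue collapses changes and drops stops", {
  g <- reference_genome("one", "GCC",
                        data.frame(gene = "g1", start = 1, end = 3,
                                   strand = "+", codon_start = 0))
  cat1 <- nonsynonymous_catalog(g)
  expect_setequal(paste0(cat1$ref_aa, cat1$codon_index, cat1$alt_aa),
                  c("A1T", "A1P", "A1S", "A1D", "A1G", "A1V"))

  cat2 <- nonsynonymous_catalog(toy_atggcc())
  expect_false(any(cat2$alt_aa == "*" | cat2$ref_aa == "*"))
  # all-noncoding genome: annotate a gene-free region via empty gene table
  g3 <- reference_genome("nc", "ACGTACGT",
                         data.frame(gene = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    codon_start = integer()))
  expect_equal(nrow(nonsynonymous_catalog(g3)), 0)
})

test_that("score attachment honours the policy", {
  g <- toy_atggcc()
  v <- enumerate_all_substitutions(g)
  tab <- data.frame(gene = "g1", ref_aa = "M", codon_index = 1,
                    alt_aa = "I", score = 0.42)
  expect_error(attach_scores(v, tab, policy = "strict"), "no score")
  sv <- suppressWarnings(attach_scores(v, tab, policy = "skip"))
  mi <- sv[sv$class == "nonsynonymous" & sv$aa_change == "M1I", ]
  expect_true(all(mi$score == 0.42))
  expect_true(all(is.na(sv$score[sv$class == "synonymous"])))
  expect_gt(attr(sv, "n_unmatched"), 0)

  full <- nonsynonymous_catalog(g)
  full$score <- 0.5
  sv2 <- attach_scores(v, full, policy = "strict")
  expect_true(all(!is.na(sv2$score[sv2$class == "nonsynonymous"])))
  expect_equal(attr(sv2, "n_unmatched"), 0)
})

test_that("overlapping genes give one consequence per gene", {
  g <- make_toy_reference(n_genes = 1, gene_lengths = 30, seed = 13,
                          overlap = TRUE)
  v <- enumerate_all_substitutions(g)
  key <- paste(v$position, v$alt)
  multi <- names(which(table(key) == 2))
  expect_gt(length(multi), 0)
  res <- resolve_variant_class(v)
  expect_equal(nrow(res), 3 * g$length)
  # ANY-nonsynonymous rule
  ex <- v[key %in% multi, ]
  for (k in unique(paste(ex$position, ex$alt))) {
    rows <- ex[paste(ex$position, ex$alt) == k, ]
    want <- if (any(rows$class == "nonsynonymous")) "nonsynonymous"
            else if (all(rows$class == "synonymous")) "synonymous"
            else "other"
    expect_equal(res$resolved_class[paste(res$position, res$alt) == k],
                 want)
  }
})
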