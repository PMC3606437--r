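#' Classify a single-nucleotide substitution
#'
#' Reports one consequence per gene covering the position, using the
#' vertebrate mitochondrial genetic code and strand-aware codon extraction
#' (minus-strand genes such as ND6 are classified on their reverse
#' complement). Positions covered by no gene's coding frame yield a single
#' `noncoding` consequence.
#'
#' Consequence classes: `synonymous` (amino acid unchanged), `nonsynonymous`
#' (amino acid changed, neither codon a stop), `stop_gain`, `stop_loss`,
#' `stop_retained` (stop codon replaced by another stop), `noncoding`.
#'
#' @param genome a [reference_genome()].
#' @param position 1-based reference coordinate.
#' @param alt substituted base, different from the reference base.
#' @return data frame with columns `gene`, `codon_index`, `ref_aa`, `alt_aa`,
#'   `class` (one row per covering gene).
#' @export
classify_substitution <- function(genome, position, alt) {
  position <- as.integer(position)
  if (position < 1L || position > genome$length)
    stop("position ", position, " outside [1, ", genome$length, "]")
  ref <- genome_base(genome, position)
  alt <- toupper(alt)
  if (!alt %in% DNA_BASES) stop("alt must be one of A, C, G, T")
  if (alt == ref) stop("alt equals the reference base at position ", position)
  classify_change(genome, position, ref, alt)
}

# Consequences of replacing base `from` by `to` at `position`, evaluated in
# the reference codon context. Neither base needs to equal the reference
# base, which lets parsimony-mapped changes on internal branches (including
# reversions) be classified consistently.
classify_change <- function(genome, position, from, to) {
  code <- mito_genetic_code()
  out <- list()
  for (i in seq_len(nrow(genome$genes))) {
    pos <- gene_coding_positions(genome, i)
    idx <- match(position, pos)
    if (is.na(idx)) next
    g <- genome$genes[i, ]
    codon_index <- (idx - 1L) %/% 3L + 1L
    codon_pos <- pos[(codon_index - 1L) * 3L + 1:3]
    codon <- vapply(codon_pos, function(p) genome_base(genome, p),
                    character(1))
    from_s <- from
    to_s <- to
    if (g$strand == "-") {
      codon <- complement_base(codon)
      from_s <- complement_base(from)
      to_s <- complement_base(to)
    }
    within <- idx - (codon_index - 1L) * 3L
    ref_codon <- codon
    ref_codon[within] <- from_s
    alt_codon <- codon
    alt_codon[within] <- to_s
    if (any(!c(ref_codon, alt_codon) %in% DNA_BASES)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g$gene, codon_index = codon_index,
        ref_aa = NA_character_, alt_aa = NA_character_,
        class = "noncoding", stringsAsFactors = FALSE)
      next
    }
    ref_aa <- translate_codon(paste(ref_codon, collapse = ""), code)
    alt_aa <- translate_codon(paste(alt_codon, collapse = ""), code)
    class <- if (ref_aa == alt_aa) {
      if (ref_aa == "*") "stop_retained" else "synonymous"
    } else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "nonsynonymous"
    out[[length(out) + 1L]] <- data.frame(
      gene = g$gene, codon_index = codon_index,
      ref_aa = ref_aa, alt_aa = alt_aa, class = class,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = NA_character_, codon_index = NA_integer_,
                      ref_aa = NA_character_, alt_aa = NA_character_,
                      class = "noncoding", stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Enumerate every possible single-nucleotide substitution
#'
#' Generates all `3 * length` substitutions of the reference (each site has
#' one transition and two transversions), classifying each against every
#' covering gene. The result has one row per (position, alt, gene)
#' consequence, ordered by position and then alt base (A < C < G < T).
#'
#' @param genome a [reference_genome()].
#' @return data frame with columns `position`, `ref`, `alt`, `type`
#'   (transition/transversion), `gene`, `codon_index`, `ref_aa`, `alt_aa`,
#'   `aa_change` (e.g. `"M1I"`), `class`, `score` (NA until
#'   [attach_scores()]).
#' @export
enumerate_all_substitutions <- function(genome) {
  rows <- vector("list", genome$length * 3L)
  k <- 0L
  for (position in seq_len(genome$length)) {
    ref <- genome_base(genome, position)
    alts <- if (ref %in% DNA_BASES) setdiff(DNA_BASES, ref) else DNA_BASES[1:3]
    for (alt in alts) {
      cons <- classify_change(genome, position, ref, alt)
      rownames(cons) <- NULL
      k <- k + 1L
      rows[[k]] <- data.frame(
        position = position, ref = ref, alt = alt,
        type = if (ref %in% DNA_BASES) unname(mutation_type(ref, alt))
               else NA_character_,
        cons, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out$aa_change <- ifelse(
    is.na(out$ref_aa), NA_character_,
    paste0(out$ref_aa, out$codon_index, out$alt_aa))
  out$score <- NA_real_
  rownames(out) <- NULL
  out[, c("position", "ref", "alt", "type", "gene", "codon_index",
          "ref_aa", "alt_aa", "aa_change", "class", "score")]
}

#' Resolve per-gene consequences to a single variant class
#'
#' A substitution covered by several (possibly overlapping) genes is
#' `nonsynonymous` if nonsynonymous in any gene, `synonymous` only if
#' synonymous in every covering gene, and `other` otherwise (stop-affecting
#' or noncoding). `other` variants are excluded from both rho filters and
#' from the selection analyses.
#'
#' @param variants data frame from [enumerate_all_substitutions()].
#' @return data frame with one row per (position, alt) and columns
#'   `position`, `ref`, `alt`, `type`, `resolved_class`, `score` (the score
#'   of the nonsynonymous consequence if attached).
#' @export
resolve_variant_class <- function(variants) {
  key <- paste(variants$position, variants$alt, sep = ":")
  split_idx <- split(seq_len(nrow(variants)), key)
  res <- lapply(split_idx, function(ii) {
    cl <- variants$class[ii]
    resolved <-
      if (any(cl == "nonsynonymous")) "nonsynonymous"
      else if (all(cl == "synonymous")) "synonymous"
      else "other"
    sc <- variants$score[ii][cl == "nonsynonymous"]
    sc <- sc[!is.na(sc)]
    data.frame(position = variants$position[ii[1]],
               ref = variants$ref[ii[1]], alt = variants$alt[ii[1]],
               type = variants$type[ii[1]], resolved_class = resolved,
               score = if (length(sc)) sc[1] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$position, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Catalogue of all possible nonsynonymous amino-acid changes
#'
#' Collapses the exhaustive enumeration to the distinct amino-acid changes
#' with class `nonsynonymous`; substitutions involving stop codons are
#' excluded. The result is the manifest one would submit to an external
#' pathogenicity predictor.
#'
#' @param genome a [reference_genome()].
#' @return data frame with columns `gene`, `ref_aa`, `codon_index`, `alt_aa`.
#' @export
nonsynonymous_catalog <- function(genome) {
  v <- enumerate_all_substitutions(genome)
  v <- v[v$class == "nonsynonymous", c("gene", "ref_aa", "codon_index",
                                       "alt_aa")]
  v <- unique(v)
  v <- v[order(v$gene, v$codon_index, v$alt_aa), ]
  rownames(v) <- NULL
  v
}

#' Load a pathogenicity score table
#'
#' @param path TSV with header columns `gene`, `ref_aa`, `codon_index`,
#'   `alt_aa`, `score` (scores are probabilities in \[0, 1\] that the
#'   amino-acid change is deleterious).
#' @return data frame usable by [attach_scores()].
#' @export
load_score_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "ref_aa", "codon_index", "alt_aa", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("score table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tab$score < 0 | tab$score > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  tab
}

#' Attach pathogenicity scores to nonsynonymous consequences
#'
#' @param variants data frame from [enumerate_all_substitutions()].
#' @param score_table data frame as returned by [load_score_table()].
#' @param policy `"strict"` errors on a nonsynonymous change missing from the
#'   table; `"skip"` leaves it unscored with a warning count.
#' @return `variants` with the `score` column filled for matched
#'   nonsynonymous rows; the number of unmatched nonsynonymous rows is
#'   attached as attribute `n_unmatched`.
#' @export
attach_scores <- function(variants, score_table,
                          policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  key <- function(d) paste(d$gene, d$ref_aa, d$codon_index, d$alt_aa,
                           sep = "|")
  lookup <- setNames(score_table$score, key(score_table))
  is_ns <- variants$class == "nonsynonymous"
  hit <- lookup[key(variants[is_ns, , drop = FALSE])]
  unmatched <- sum(is.na(hit))
  if (unmatched > 0L) {
    missing_changes <- unique(
      variants$aa_change[is_ns][is.na(hit)])
    if (policy == "strict")
      stop("no score for nonsynonymous change(s): ",
           paste(head(missing_changes, 10), collapse = ", "))
    warning(unmatched, " nonsynonymous consequence(s) left unscored")
  }
  variants$score[is_ns] <- unname(hit)
  attr(variants, "n_unmatched") <- unmatched
  variants
}
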