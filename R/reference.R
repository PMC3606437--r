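#' Construct an annotated mitochondrial reference genome
#'
#' The container used throughout the package for a circular (or linear)
#' mtDNA reference with protein-coding gene annotation. Coordinates are
#' 1-based inclusive in the original reference numbering; no re-origin is
#' applied. A gene whose `start > end` is interpreted as wrapping the
#' circular origin.
#'
#' @param name label for the genome.
#' @param sequence nucleotide string over A/C/G/T (upper-cased on input).
#' @param genes data frame with columns `gene`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `codon_start` (offset 0/1/2 into the span before the
#'   first complete codon) and optionally `incomplete_stop` (logical; the
#'   trailing partial stop codon, completed by polyadenylation in vivo, is
#'   excluded from classification).
#' @param circular logical; circular molecule (default `TRUE`).
#' @param ambiguity `"error"` to reject non-ACGT characters, `"mask"` to
#'   replace them by `N` and treat those sites as unclassifiable noncoding.
#' @return An object of class `mito_reference` with elements `name`,
#'   `sequence`, `length`, `circular`, `genes`.
#' @export
reference_genome <- function(name, sequence, genes, circular = TRUE,
                             ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("reference sequence is empty")
  bad <- gsub("[ACGT]", "", sequence)
  if (nchar(bad) > 0L) {
    if (ambiguity == "error")
      stop("non-ACGT characters in reference: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
    sequence <- gsub("[^ACGT]", "N", sequence)
  }
  genes <- validate_genes(genes, nchar(sequence), circular)
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence), circular = circular,
                 genes = genes),
            class = "mito_reference")
}

validate_genes <- function(genes, len, circular) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "strand", "codon_start")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(genes$incomplete_stop))
    genes$incomplete_stop <- rep(FALSE, nrow(genes))
  genes$incomplete_stop <- as.logical(genes$incomplete_stop)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$codon_start <- as.integer(genes$codon_start)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$start < 1L || g$start > len || g$end < 1L || g$end > len)
      stop("gene ", g$gene, ": span outside sequence [1, ", len, "]")
    if (!g$strand %in% c("+", "-"))
      stop("gene ", g$gene, ": strand must be '+' or '-'")
    if (!g$codon_start %in% 0:2)
      stop("gene ", g$gene, ": codon_start must be 0, 1 or 2")
    wraps <- g$start > g$end
    if (wraps && !circular)
      stop("gene ", g$gene, ": start > end on a linear reference")
    span <- if (wraps) len - g$start + 1L + g$end else g$end - g$start + 1L
    coding <- span - g$codon_start
    if (coding %% 3L != 0L && !g$incomplete_stop)
      stop("gene ", g$gene, ": coding length ", coding,
           " not a multiple of 3 (set incomplete_stop if the terminal stop ",
           "codon is completed by polyadenylation)")
  }
  genes
}

#' Load an annotated reference from FASTA and a gene table
#'
#' Reads a single-record FASTA plus a tab-separated annotation table with
#' columns `gene`, `start`, `end`, `strand`, `codon_start` and optionally
#' `incomplete_stop`, and returns a validated [reference_genome()].
#'
#' @param fasta_path path to a FASTA file containing exactly one record.
#' @param annotation_path path to the gene annotation TSV (header required).
#' @param circular,ambiguity passed to [reference_genome()].
#' @return A `mito_reference` object.
#' @export
load_reference <- function(fasta_path, annotation_path, circular = TRUE,
                           ambiguity = c("error", "mask")) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(annotation_path))
    stop("annotation not found: ", annotation_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("expected exactly one FASTA record, found ", length(seqs))
  genes <- read.delim(annotation_path, stringsAsFactors = FALSE)
  reference_genome(names(seqs)[1], as.character(seqs[[1]]), genes,
                   circular = circular, ambiguity = match.arg(ambiguity))
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("mito_reference '", x$name, "': ", x$length, " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

# Genomic positions of the classified coding region of gene i, in reading
# order along the coding strand. codon_start offset and any trailing partial
# (incomplete stop) codon are excluded, so the result length is always a
# multiple of 3.
gene_coding_positions <- function(genome, i) {
  g <- genome$genes[i, ]
  pos <- if (g$start > g$end) {
    c(g$start:genome$length, 1L:g$end)
  } else {
    g$start:g$end
  }
  if (g$strand == "-") pos <- rev(pos)
  if (g$codon_start > 0L) pos <- pos[-seq_len(g$codon_start)]
  extra <- length(pos) %% 3L
  if (extra > 0L) pos <- pos[seq_len(length(pos) - extra)]
  pos
}

genome_base <- function(genome, position) {
  substring(genome$sequence, position, position)
}
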