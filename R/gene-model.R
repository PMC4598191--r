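# Transcript models and variant effect classification. The model carries
# explicit transcript/exon/CDS intervals (1-based inclusive) plus the genome
# sequence, which is all the classifier needs: splice-dinucleotide detection,
# frame arithmetic for indels, and codon translation for SNVs.

#' Construct a gene model
#'
#' @param transcripts tibble `tx, gene, chrom, strand, tx_start, tx_end`
#'   (1-based inclusive; `strand` is `"+"` or `"-"`).
#' @param exons tibble `tx, start, end`.
#' @param cds tibble `tx, start, end` (coding intervals; total length per
#'   transcript must be a multiple of 3).
#' @param genome named character vector of chromosome sequences.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(transcripts, exons, cds, genome) {
  stopifnot(all(transcripts$strand %in% c("+", "-")))
  cds_len <- cds %>% group_by(.data$tx) %>%
    summarise(len = sum(.data$end - .data$start + 1L))
  if (any(cds_len$len %% 3L != 0L)) {
    abort("CDS length must be a multiple of 3 for every transcript")
  }
  structure(
    list(transcripts = as_tibble(transcripts), exons = as_tibble(exons),
         cds = as_tibble(cds), genome = genome),
    class = "gene_model"
  )
}

complement_bases <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

genome_bases <- function(genome, chrom, pos) {
  seq <- genome[[chrom]]
  vapply(pos, function(p) substr(seq, p, p), character(1))
}

# Splice dinucleotide positions of one transcript: the two intronic bases
# flanking each internal exon edge.
splice_positions <- function(exons, tx_start, tx_end) {
  pos <- integer(0)
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    if (s > tx_start) pos <- c(pos, s - 2L, s - 1L)
    if (e < tx_end) pos <- c(pos, e + 1L, e + 2L)
  }
  pos
}

overlaps_any <- function(lo, hi, starts, ends) {
  any(pmax(lo, starts) <= pmin(hi, ends))
}

classify_in_tx <- function(chrom, pos, ref, alt, tx_row, exons, cds, genome,
                           large_indel) {
  lo <- pos; hi <- pos + nchar(ref) - 1L
  sp <- splice_positions(exons, tx_row$tx_start, tx_row$tx_end)
  if (length(sp) > 0 && any(sp >= lo & sp <= hi)) return("SPLICE_DINUCLEOTIDE")
  in_cds <- nrow(cds) > 0 && overlaps_any(lo, hi, cds$start, cds$end)
  if (in_cds) {
    if (nchar(ref) != nchar(alt)) {
      len <- abs(nchar(ref) - nchar(alt))
      if (len %% 3L != 0L) return("FRAMESHIFT_INDEL")
      if (len >= large_indel) return("LARGE_CODING_INDEL")
      return("NONFRAMESHIFT_INDEL")
    }
    if (nchar(ref) == 1L) {
      return(classify_snv_codon(chrom, pos, alt, tx_row$strand, cds, genome))
    }
    return("OTHER")  # equal-length multi-base substitution
  }
  if (overlaps_any(lo, hi, exons$start, exons$end)) return("UTR")
  "INTRONIC"
}

classify_snv_codon <- function(chrom, pos, alt, strand, cds, genome) {
  cds_pos <- unlist(Map(seq.int, cds$start, cds$end))
  cds_pos <- sort(cds_pos)
  if (strand == "-") cds_pos <- rev(cds_pos)  # transcription order
  i <- match(pos, cds_pos)
  if (is.na(i)) return("OTHER")  # unreachable given the in_cds guard
  ci <- (i - 1L) %/% 3L
  codon_idx <- (ci * 3L + 1L):(ci * 3L + 3L)
  bases <- genome_bases(genome, chrom, cds_pos[codon_idx])
  if (strand == "-") bases <- complement_bases(bases)
  codon_ref <- toupper(paste(bases, collapse = ""))
  alt_base <- if (strand == "-") complement_bases(alt) else alt
  bases[i - ci * 3L] <- alt_base
  codon_alt <- toupper(paste(bases, collapse = ""))
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon_ref])
  aa_alt <- unname(code[codon_alt])
  if (is.na(aa_ref) || is.na(aa_alt)) return("OTHER")
  if (aa_ref != "*" && aa_alt == "*") return("NONSENSE")
  if (aa_ref == "*" && aa_alt != "*") return("NONSTOP")
  if (aa_ref == aa_alt) return("SYNONYMOUS")
  "MISSENSE"
}

#' Classify variant effects against a gene model
#'
#' Assigns each variant its gene-level effect class: the most severe class
#' across overlapping transcripts under the fixed severity order
#' [EFFECT_LEVELS]. Splice classification applies only to the two intronic
#' bases flanking each internal exon edge; coding SNVs are translated through
#' the standard genetic code; coding indels are classified by length modulo 3
#' and, for in-frame events, by the large-indel size threshold. Variants
#' outside every transcript are `INTERGENIC`.
#'
#' @param df tibble with `chrom, pos, ref, alt`.
#' @param gene_model a [gene_model()].
#' @param large_indel minimum in-frame coding indel length (bp) classified as
#'   `LARGE_CODING_INDEL` (default 50).
#' @return `df` with `effect`, `gene`, `transcript` columns added.
#' @export
classify_effect <- function(df, gene_model, large_indel = 50) {
  gm <- gene_model
  n <- nrow(df)
  effect <- rep("INTERGENIC", n)
  gene <- rep(NA_character_, n)
  transcript <- rep(NA_character_, n)
  for (r in seq_len(n)) {
    lo <- df$pos[r]; hi <- df$pos[r] + nchar(df$ref[r]) - 1L
    txs <- gm$transcripts %>%
      filter(.data$chrom == df$chrom[r], .data$tx_start <= hi, .data$tx_end >= lo)
    if (nrow(txs) == 0) next
    best_lvl <- length(EFFECT_LEVELS) + 1L
    for (t in seq_len(nrow(txs))) {
      tx_row <- txs[t, ]
      cls <- classify_in_tx(
        df$chrom[r], df$pos[r], df$ref[r], df$alt[r], tx_row,
        filter(gm$exons, .data$tx == tx_row$tx),
        filter(gm$cds, .data$tx == tx_row$tx),
        gm$genome, large_indel
      )
      lvl <- match(cls, EFFECT_LEVELS)
      if (lvl < best_lvl) {
        best_lvl <- lvl
        effect[r] <- cls
        gene[r] <- tx_row$gene
        transcript[r] <- tx_row$tx
      }
    }
  }
  df$effect <- effect
  df$gene <- gene
  df$transcript <- transcript
  df
}

#' Toy three-gene model for fixtures and examples
#'
#' Two autosomes plus X with one 3-exon gene each (one on the minus strand),
#' designed CDS sequences (ATG start, TAA stop, stop-free interior with
#' glutamine codons available for nonsense probes), and random intergenic
#' background. Deterministic for a given seed.
#'
#' @param seed integer seed for the background sequence.
#' @return a [gene_model()].
#' @export
toy_gene_model <- function(seed = 2026) {
  transcripts <- tibble(
    tx = c("TOYG1-T1", "TOYG2-T1", "TOYG3-T1"),
    gene = c("TOYG1", "TOYG2", "TOYG3"),
    chrom = c("1", "2", "X"),
    strand = c("+", "-", "+"),
    tx_start = c(1000L, 10000L, 5000L),
    tx_end = c(2999L, 11999L, 5999L)
  )
  exons <- tibble(
    tx = c(rep("TOYG1-T1", 3), rep("TOYG2-T1", 3), "TOYG3-T1"),
    start = c(1000L, 1500L, 2500L, 10000L, 11000L, 11800L, 5000L),
    end = c(1199L, 1799L, 2999L, 10499L, 11399L, 11999L, 5999L)
  )
  cds <- tibble(
    tx = c(rep("TOYG1-T1", 3), rep("TOYG2-T1", 3), "TOYG3-T1"),
    start = c(1101L, 1500L, 2500L, 10100L, 11000L, 11800L, 5101L),
    end = c(1199L, 1799L, 2601L, 10499L, 11399L, 11899L, 5400L)
  )
  lens <- c(`1` = 100000L, `2` = 50000L, X = 50000L)
  genome <- local_rng(seed, {
    vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(genome) <- names(lens)
  interior <- c("CAG", "GCT", "AAA", "TGC", "CTG", "GAA")  # no stop codons
  for (txid in unique(cds$tx)) {
    tr <- transcripts[transcripts$tx == txid, ]
    cd <- cds[cds$tx == txid, ]
    pos_asc <- sort(unlist(Map(seq.int, cd$start, cd$end)))
    n_codon <- length(pos_asc) / 3L
    codons <- c("ATG", rep(interior, length.out = n_codon - 2L), "TAA")
    letters_tx <- strsplit(paste(codons, collapse = ""), "")[[1]]
    if (tr$strand == "+") {
      letters_asc <- letters_tx
    } else {
      letters_asc <- rev(complement_bases(letters_tx))
    }
    seq <- genome[[tr$chrom]]
    for (k in seq_along(pos_asc)) {
      substr(seq, pos_asc[k], pos_asc[k]) <- letters_asc[k]
    }
    genome[[tr$chrom]] <- seq
  }
  gene_model(transcripts, exons, cds, genome)
}
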