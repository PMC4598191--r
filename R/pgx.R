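# Star-allele diplotype assignment from unphased, confidently called
# genotypes, and single-variant drug-response annotation.
#
# The caller is deliberately conservative: haplotypes are resolved only as
# far as the confident genotypes allow. Confident homozygous calls pin both
# haplotypes (the "skeleton"); heterozygous calls are expanded into every
# complementary assignment; positions that are uncovered, uncalled, or
# low-confidence stay UNKNOWN, and any star allele consistent with the known
# entries remains a candidate (tag variants are not disambiguated).

#' Read a star-allele definition table
#'
#' Long TSV `gene allele chrom pos ref alt`: one row per non-reference
#' defining position of each named allele; positions absent from an allele's
#' rows are reference. The `*1` reference allele needs no rows.
#' @param path TSV with header.
#' @export
read_star_definitions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}

# Allele-by-position matrix of allele strings for one gene. Rows = star
# alleles (always including *1 = all reference), columns = defining
# positions; entries are the nucleotide strings carried there.
star_allele_matrix <- function(definitions, gene) {
  defs <- filter(definitions, .data$gene == !!gene)
  if (nrow(defs) == 0) abort(paste0("no star-allele definitions for gene ", gene))
  univ <- defs %>% distinct(.data$chrom, .data$pos, .data$ref) %>% arrange(.data$pos)
  if (anyDuplicated(univ$pos) > 0) {
    abort("conflicting reference alleles at a defining position")
  }
  alleles <- union("*1", unique(defs$allele))
  M <- matrix(rep(univ$ref, each = length(alleles)),
              nrow = length(alleles),
              dimnames = list(alleles, as.character(univ$pos)))
  for (r in seq_len(nrow(defs))) {
    M[defs$allele[r], as.character(defs$pos[r])] <- defs$alt[r]
  }
  dup <- duplicated(apply(M, 1, paste, collapse = "|"))
  if (any(dup)) {
    abort(paste0("star alleles with identical haplotypes in gene ", gene, ": ",
                 paste(rownames(M)[dup], collapse = ", ")))
  }
  attr(M, "chrom") <- univ$chrom[1]
  M
}

#' Build the skeleton haplotype pair for one gene
#'
#' Both haplotypes carry the shared nucleotide at every confidently
#' homozygous position (reference or alternate); heterozygous positions are
#' left open for enumeration; positions with no confident call — uncovered,
#' missing, or low-confidence — are UNKNOWN (`NA`) on both haplotypes.
#'
#' @param genotypes calls tibble rows for one sample (columns `pos, ref, alt,
#'   a1, a2, status`); only rows at defining positions are consulted.
#' @param allele_matrix output of `star_allele_matrix()` (internal) or any
#'   matrix whose column names are the defining positions and whose `"*1"`
#'   row holds the reference alleles.
#' @return list with `hapA`, `hapB` (named character vectors over defining
#'   positions, `NA` = unknown) and `het_positions`.
#' @export
build_skeleton <- function(genotypes, allele_matrix) {
  positions <- colnames(allele_matrix)
  ref_row <- allele_matrix["*1", ]
  hapA <- hapB <- setNames(rep(NA_character_, length(positions)), positions)
  het <- list()
  for (p in positions) {
    g <- genotypes[as.character(genotypes$pos) == p, ]
    if (nrow(g) == 0) next  # uncovered -> UNKNOWN
    g <- g[1, ]
    if (g$status != "CALLED") next  # not confidently called -> UNKNOWN
    allele_str <- function(code) {
      if (is.na(code)) NA_character_
      else if (code == 0L) g$ref
      else g$alt
    }
    s1 <- allele_str(g$a1); s2 <- allele_str(g$a2)
    if (is.na(s1) || is.na(s2)) next
    if (s1 == s2) {
      hapA[p] <- hapB[p] <- s1
    } else {
      het[[p]] <- c(s1, s2)
    }
  }
  list(hapA = hapA, hapB = hapB, het_positions = het)
}

#' Enumerate complementary haplotype pairs over heterozygous positions
#'
#' With h heterozygous positions there are exactly `max(1, 2^(h-1))` distinct
#' unordered complementary pairs: the first heterozygous position is fixed to
#' haplotype A to remove mirror duplicates. Above `het_cap` heterozygous
#' positions the expansion is refused — such calls are left to a human
#' curator rather than reported at low confidence.
#'
#' @param skeleton output of [build_skeleton()].
#' @param het_cap maximum number of heterozygous positions (default 12).
#' @return list of haplotype pairs, each `list(hapA =, hapB =)`.
#' @export
enumerate_diplotypes <- function(skeleton, het_cap = 12) {
  het <- skeleton$het_positions
  h <- length(het)
  if (h > het_cap) {
    abort(paste0(h, " heterozygous defining positions exceeds the cap (",
                 het_cap, "); resolve this gene by manual curation"))
  }
  if (h == 0) return(list(list(hapA = skeleton$hapA, hapB = skeleton$hapB)))
  het_pos <- names(het)
  n_pairs <- 2^(h - 1)
  out <- vector("list", n_pairs)
  for (m in seq_len(n_pairs) - 1L) {
    hapA <- skeleton$hapA
    hapB <- skeleton$hapB
    # first het position fixed: allele 1 to hapA
    hapA[het_pos[1]] <- het[[1]][1]
    hapB[het_pos[1]] <- het[[1]][2]
    if (h > 1) {
      bits <- as.integer(intToBits(m))[seq_len(h - 1)]
      for (k in 2:h) {
        pick <- bits[k - 1] + 1L
        hapA[het_pos[k]] <- het[[k]][pick]
        hapB[het_pos[k]] <- het[[k]][3L - pick]
      }
    }
    out[[m + 1L]] <- list(hapA = hapA, hapB = hapB)
  }
  out
}

# Star alleles compatible with one (possibly partially unknown) haplotype:
# all alleles equal to it at every known position. A fully known haplotype
# therefore matches at most the alleles identical to it.
compatible_alleles <- function(hap, allele_matrix) {
  known <- !is.na(hap)
  if (!any(known)) return(rownames(allele_matrix))
  keep <- apply(allele_matrix[, known, drop = FALSE], 1,
                function(a) all(a == hap[known]))
  rownames(allele_matrix)[keep]
}

#' Perfect-match star-allele search over enumerated haplotype pairs
#'
#' Each haplotype is matched against the gene's definitions; a haplotype with
#' unknown positions yields the set of alleles identical at all known
#' positions. A pair's candidates are the unordered cross-product of its
#' members' match sets; pairs in which either member matches nothing are
#' reported as raw haplotypes. Status: `RESOLVED` (exactly one candidate star
#' pair), `AMBIGUOUS` (two or more; all are reported), or `UNASSIGNED` (no
#' perfect match anywhere).
#'
#' @param pairs list from [enumerate_diplotypes()].
#' @param allele_matrix the gene's allele-by-position matrix.
#' @return list with `status`, `candidates` (character vector like
#'   `"*1/*2"`), `raw_pairs`, `unknown_positions`.
#' @export
match_star_alleles <- function(pairs, allele_matrix) {
  cands <- character(0)
  raw <- list()
  for (pr in pairs) {
    mA <- compatible_alleles(pr$hapA, allele_matrix)
    mB <- compatible_alleles(pr$hapB, allele_matrix)
    if (length(mA) == 0 || length(mB) == 0) {
      raw[[length(raw) + 1]] <- pr
      next
    }
    for (a in mA) for (b in mB) {
      pair <- sort(c(a, b))
      cands <- c(cands, paste(pair[1], pair[2], sep = "/"))
    }
  }
  cands <- sort(unique(cands))
  status <- if (length(cands) == 1) "RESOLVED"
            else if (length(cands) >= 2) "AMBIGUOUS"
            else "UNASSIGNED"
  unknown <- names(pairs[[1]]$hapA)[is.na(pairs[[1]]$hapA) & is.na(pairs[[1]]$hapB)]
  list(status = status, candidates = cands, raw_pairs = raw,
       unknown_positions = unknown)
}

#' Call star-allele diplotypes for one sample
#'
#' Runs skeleton construction, complementary-haplotype enumeration, and the
#' perfect-match search for each requested gene.
#'
#' @param calls long calls tibble.
#' @param definitions star-allele definition tibble (see
#'   [read_star_definitions()]).
#' @param sample sample ID.
#' @param genes genes to call (default: all in `definitions`).
#' @param het_cap passed to [enumerate_diplotypes()].
#' @return tibble `gene, status, n_candidates, candidates (list),
#'   unknown_positions (list), n_raw_pairs`, class `star_calls`.
#' @export
call_star_alleles <- function(calls, definitions, sample,
                              genes = NULL, het_cap = 12) {
  genes <- genes %||% unique(definitions$gene)
  my <- filter(calls, .data$sample == !!sample)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    M <- star_allele_matrix(definitions, g)
    gt <- filter(my, .data$chrom == attr(M, "chrom"),
                 as.character(.data$pos) %in% colnames(M))
    sk <- build_skeleton(gt, M)
    pairs <- enumerate_diplotypes(sk, het_cap = het_cap)
    res <- match_star_alleles(pairs, M)
    rows[[i]] <- tibble(
      gene = g, status = res$status,
      n_candidates = length(res$candidates),
      candidates = list(res$candidates),
      unknown_positions = list(res$unknown_positions),
      n_raw_pairs = length(res$raw_pairs)
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("star_calls", class(out))
  out
}

#' Single-variant drug-response annotation
#'
#' Joins carried variants against a knowledge-base table and emits
#' associations whose evidence level is at least as strong as `min_level` on
#' the ordered scale 1A > 1B > 2A > 2B > 3 > 4. Rows with unrecognized levels
#' are skipped with a warning; genotypes not carrying the alternate allele
#' are never annotated.
#'
#' @param calls long calls tibble.
#' @param kb tibble `chrom, pos, ref, alt, drug, level, annotation`.
#' @param min_level weakest evidence level to report (default `"2B"`).
#' @param sample optional sample ID filter.
#' @return tibble of emitted associations with genotype columns.
#' @export
annotate_pgx_variants <- function(calls, kb, min_level = "2B", sample = NULL) {
  if (!min_level %in% PGX_EVIDENCE_LEVELS) abort("unknown min_level")
  bad <- !kb$level %in% PGX_EVIDENCE_LEVELS
  if (any(bad)) {
    warn(paste0("skipping knowledge-base rows with unknown evidence level: ",
                paste(unique(kb$level[bad]), collapse = ", ")))
    kb <- kb[!bad, ]
  }
  kb$key <- variant_key(kb$chrom, kb$pos, kb$ref, kb$alt)
  keep <- match(kb$level, PGX_EVIDENCE_LEVELS) <= match(min_level, PGX_EVIDENCE_LEVELS)
  kb <- kb[keep, c("key", "drug", "level", "annotation")]
  df <- calls
  if (!is.null(sample)) df <- filter(df, .data$sample == !!sample)
  df <- filter(df, .data$status == "CALLED", carries_alt(.data$a1, .data$a2))
  inner_join(df, kb, by = "key", relationship = "many-to-many")
}
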