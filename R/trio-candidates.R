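# The five trio candidate-variant discovery modes, run downstream of the HMM
# so that modes 1-4 only report events from good-data regions.

called <- function(status) status == "CALLED"
is_het01 <- function(a1, a2) (a1 == 0L & a2 == 1L) | (a1 == 1L & a2 == 0L)
is_hom <- function(a1, a2, allele) a1 == allele & a2 == allele
carries_alt <- function(a1, a2) a1 == 1L | a2 == 1L

rare_col <- function(tw, maf_threshold) {
  if (any(paste0("maf_", FREQ_SOURCES) %in% names(tw))) {
    is_rare(tw, maf_threshold)
  } else {
    rep(TRUE, nrow(tw))  # unannotated input: no frequency evidence against
  }
}

#' Apparent de novo variants
#'
#' Sites in GOOD regions where both parents are confidently called
#' homozygous-reference and the child confidently carries a heterozygous
#' alternate allele. In strict mode (default) any parental `NO_CALL` or
#' `LOW_CONFIDENCE` disqualifies the site; lenient mode tolerates parental
#' `LOW_CONFIDENCE` hom-ref calls.
#'
#' @param tw trio-wide tibble from [trio_wide()] (optionally annotated).
#' @param segments HMM segments (or a `trio_decode`); sites on contigs with
#'   no segments count as GOOD.
#' @param strict require parents confidently CALLED (default TRUE).
#' @return subset of `tw` with `mode = "de_novo"`.
#' @export
find_de_novo <- function(tw, segments, strict = TRUE) {
  ok_parent <- if (strict) {
    called(tw$f_status) & called(tw$m_status)
  } else {
    tw$f_status != "NO_CALL" & tw$m_status != "NO_CALL"
  }
  hit <- ok_parent & called(tw$c_status) &
    is_hom(tw$f_a1, tw$f_a2, 0L) & is_hom(tw$m_a1, tw$m_a2, 0L) &
    is_het01(tw$c_a1, tw$c_a2) &
    region_state(tw$chrom, tw$pos, segments) == "GOOD"
  mutate(tw[which(hit), ], mode = "de_novo")
}

# Which parent could have transmitted the child's alternate allele, over all
# consistent transmission assignments (one allele from each parent
# reproducing the child genotype)? The alt is transmissible from the father
# only if the mother can simultaneously supply the child's other allele.
# Returns "father", "mother", "both", or "neither" per heterozygous child
# site; NA when a parental genotype is not confidently called.
alt_origin <- function(tw) {
  other <- ifelse(tw$c_a1 == 1L, tw$c_a2, tw$c_a1)
  f_possible <- carries_alt(tw$f_a1, tw$f_a2) &
    (tw$m_a1 == other | tw$m_a2 == other)
  m_possible <- carries_alt(tw$m_a1, tw$m_a2) &
    (tw$f_a1 == other | tw$f_a2 == other)
  case_when(
    !called(tw$f_status) | !called(tw$m_status) ~ NA_character_,
    f_possible & m_possible ~ "both",
    f_possible ~ "father",
    m_possible ~ "mother",
    TRUE ~ "neither"
  )
}

#' Compound-heterozygote candidate pairs
#'
#' For every gene, all unordered pairs of child-heterozygous variants in GOOD
#' regions where at least one member of the pair is rare. Phase is inferred
#' from parental transmission alone: a pair is `TRANS_CONFIRMED` when one
#' variant can only have come from the father and the other only from the
#' mother; pairs provably in cis (both alternate alleles transmissible from
#' only the same single parent) are excluded; every other pair is reported as
#' `PHASE_UNKNOWN` rather than silently dropped.
#'
#' @param tw annotated trio-wide tibble (needs `gene` and `maf_*` columns).
#' @param segments HMM segments.
#' @param maf_threshold rarity threshold (default 0.01).
#' @return tibble `gene, key1, key2, phase, rare1, rare2`.
#' @export
find_compound_het <- function(tw, segments, maf_threshold = 0.01) {
  tw <- mutate(tw,
               .rare = rare_col(tw, maf_threshold),
               .origin = alt_origin(tw))
  ch <- tw %>%
    filter(called(.data$c_status), is_het01(.data$c_a1, .data$c_a2),
           !is.na(.data$gene),
           region_state(.data$chrom, .data$pos, segments) == "GOOD")
  out <- list()
  for (g in unique(ch$gene)) {
    v <- ch[ch$gene == g, ]
    if (nrow(v) < 2) next
    pr <- combn(nrow(v), 2)
    for (p in seq_len(ncol(pr))) {
      i <- pr[1, p]; j <- pr[2, p]
      if (!(v$.rare[i] || v$.rare[j])) next
      oi <- v$.origin[i]; oj <- v$.origin[j]
      phase <- if (!is.na(oi) && !is.na(oj) &&
                   ((oi == "father" && oj == "mother") ||
                    (oi == "mother" && oj == "father"))) {
        "TRANS_CONFIRMED"
      } else if (!is.na(oi) && !is.na(oj) && oi == oj &&
                 oi %in% c("father", "mother")) {
        "CIS"
      } else {
        "PHASE_UNKNOWN"
      }
      if (phase == "CIS") next
      out[[length(out) + 1]] <- tibble(
        gene = g, key1 = v$key[i], key2 = v$key[j], phase = phase,
        rare1 = v$.rare[i], rare2 = v$.rare[j]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(gene = character(), key1 = character(), key2 = character(),
                  phase = character(), rare1 = logical(), rare2 = logical()))
  }
  distinct(bind_rows(out))
}

#' Rare homozygous-alternate candidates
#'
#' Child confidently homozygous for a rare alternate allele in a GOOD region,
#' with both parental genotypes Mendelian-consistent (each parent confidently
#' carries at least one alternate allele). Hom-alt children whose parents do
#' not both carry the allele are inheritance abnormalities, handled by the
#' HMM / hemizygosity channels instead.
#'
#' @inheritParams find_compound_het
#' @return subset of `tw` with `mode = "rare_homozygous"`.
#' @export
find_rare_homozygous <- function(tw, segments, maf_threshold = 0.01) {
  rare <- rare_col(tw, maf_threshold)
  hit <- called(tw$c_status) & called(tw$f_status) & called(tw$m_status) &
    is_hom(tw$c_a1, tw$c_a2, 1L) &
    carries_alt(tw$f_a1, tw$f_a2) & carries_alt(tw$m_a1, tw$m_a2) &
    rare &
    region_state(tw$chrom, tw$pos, segments) == "GOOD"
  mutate(tw[which(hit), ], mode = "rare_homozygous")
}

#' Apparent hemizygosity over deletions
#'
#' Child variants that look homozygous-alternate while only one parent
#' carries the alternate allele (the other confidently hom-ref) — an
#' inheritance abnormality unless the non-transmitting haplotype is deleted.
#' A site is reported when it overlaps a supplied deletion interval; the
#' interval list is not lineage-resolved, so any overlapping deletion
#' qualifies and the call is flagged putative. Candidates for loss of
#' function.
#'
#' @param tw trio-wide tibble.
#' @param deletions tibble `chrom, start, end` (0-based half-open), e.g. from
#'   [read_deletion_intervals()]; may be empty.
#' @param segments optional HMM segments; when supplied, only GOOD-region
#'   sites are reported.
#' @return subset of `tw` with `mode`, `deletion_start`, `deletion_end`.
#' @export
find_hemizygous <- function(tw, deletions, segments = NULL) {
  one_parent <- (carries_alt(tw$f_a1, tw$f_a2) & is_hom(tw$m_a1, tw$m_a2, 0L)) |
    (carries_alt(tw$m_a1, tw$m_a2) & is_hom(tw$f_a1, tw$f_a2, 0L))
  hit <- called(tw$c_status) & called(tw$f_status) & called(tw$m_status) &
    is_hom(tw$c_a1, tw$c_a2, 1L) & one_parent
  if (!is.null(segments)) {
    hit <- hit & region_state(tw$chrom, tw$pos, segments) == "GOOD"
  }
  idx <- interval_lookup(tw$chrom, tw$pos, deletions)
  hit <- hit & !is.na(idx)
  out <- tw[which(hit), ]
  out$deletion_start <- deletions$start[idx[which(hit)]]
  out$deletion_end <- deletions$end[idx[which(hit)]]
  mutate(out, mode = "hemizygous_putative")
}

#' Dominant-with-reduced-penetrance candidates
#'
#' Rare child-carried variants in known inherited-disease genes. Because
#' penetrance is assumed reduced, inheritance from an unaffected carrier
#' parent is allowed: no segregation requirement is imposed, and the mode is
#' not restricted by HMM region (it screens a curated gene set rather than
#' genome-wide inheritance patterns).
#'
#' @param tw annotated trio-wide tibble (needs `gene` and `maf_*` columns).
#' @param disease_genes character vector of inherited-disease gene symbols.
#' @param maf_threshold rarity threshold.
#' @return subset of `tw` with `mode = "ad_reduced_penetrance"`.
#' @export
find_ad_reduced_penetrance <- function(tw, disease_genes, maf_threshold = 0.01) {
  rare <- rare_col(tw, maf_threshold)
  hit <- called(tw$c_status) & carries_alt(tw$c_a1, tw$c_a2) &
    rare & !is.na(tw$gene) & tw$gene %in% disease_genes
  mutate(tw[which(hit), ], mode = "ad_reduced_penetrance")
}

#' Run all five trio candidate modes
#'
#' @param tw annotated trio-wide tibble.
#' @param segments HMM segments or a `trio_decode`.
#' @param deletions deletion intervals for the hemizygosity mode (may be
#'   empty).
#' @param disease_genes gene set for the dominant-reduced-penetrance mode
#'   (may be empty).
#' @param maf_threshold rarity threshold shared by the modes that use one.
#' @return named list of candidate tibbles
#'   (`de_novo, compound_het, rare_homozygous, hemizygous,
#'   ad_reduced_penetrance`), class `trio_candidates`.
#' @export
trio_candidates <- function(tw, segments, deletions = NULL,
                            disease_genes = character(), maf_threshold = 0.01) {
  if (is.null(deletions)) {
    deletions <- tibble(chrom = character(), start = integer(), end = integer())
  }
  structure(
    list(
      de_novo = find_de_novo(tw, segments),
      compound_het = find_compound_het(tw, segments, maf_threshold),
      rare_homozygous = find_rare_homozygous(tw, segments, maf_threshold),
      hemizygous = find_hemizygous(tw, deletions, segments),
      ad_reduced_penetrance = find_ad_reduced_penetrance(tw, disease_genes, maf_threshold)
    ),
    class = "trio_candidates"
  )
}

#' @export
print.trio_candidates <- function(x, ...) {
  cat("<trio_candidates>\n")
  for (m in names(x)) cat(sprintf("  %-22s %d\n", m, nrow(x[[m]])))
  invisible(x)
}
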