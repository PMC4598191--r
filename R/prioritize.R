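# Two-track, four-tier prioritization. Both tracks evaluate tiers in order
# 1 -> 4 with first match winning; the retained review set is tiers 1-3,
# optionally thinned by the local-cohort frequency filter.
#
# Reported track (variants present in the disease-mutation catalog):
#   tier 1  loss of function, no frequency filter
#   tier 2  rare (<= 1% in every survey with data)
#   tier 3  missense / non-frameshift indel, no frequency filter
#   tier 4  everything else
# Novel track (not in the catalog; only rare variants in monogenic-disease
# genes are eligible, others are EXCLUDED):
#   tier 1  loss of function
#   tier 2  missense with conservation consensus, or non-frameshift indel
#   tier 3  missense with pathogenicity consensus (>= 3 damaging votes)
#   tier 4  everything else eligible

indel_len <- function(ref, alt) abs(nchar(ref) - nchar(alt))

#' Tier a variant on the reported-catalog track
#'
#' @param df annotated tibble (see [annotate_variants()]).
#' @param maf_threshold rarity threshold (default 0.01).
#' @param threshold_large large-indel LOF threshold in bp.
#' @return tibble `track, tier, rationale` aligned with `df`; `tier` is
#'   `NA` (excluded) for variants not in the reported catalog.
#' @export
tier_reported <- function(df, maf_threshold = 0.01, threshold_large = 50) {
  lof <- is_lof(df$effect, indel_len(df$ref, df$alt), threshold_large)
  rare <- is_rare(df, maf_threshold)
  t3_class <- df$effect %in% c("MISSENSE", "NONFRAMESHIFT_INDEL")
  tier <- rep(NA_integer_, nrow(df))
  rationale <- rep("not_reported", nrow(df))
  el <- df$reported
  tier[el] <- 4L
  rationale[el] <- "reported"
  hit <- el & t3_class
  tier[hit] <- 3L
  rationale[hit] <- "reported;missense_or_nonframeshift"
  hit <- el & rare
  tier[hit] <- 2L
  rationale[hit] <- "reported;rare"
  hit <- el & lof
  tier[hit] <- 1L
  rationale[hit] <- "reported;lof"
  tibble(track = "REPORTED", tier = tier, rationale = rationale)
}

#' Tier a variant on the novel track
#'
#' Only previously unreported, rare variants in monogenic-disease genes are
#' eligible; everything else is excluded (`tier = NA`).
#'
#' @inheritParams tier_reported
#' @return tibble `track, tier, rationale` aligned with `df`.
#' @export
tier_novel <- function(df, maf_threshold = 0.01, threshold_large = 50) {
  lof <- is_lof(df$effect, indel_len(df$ref, df$alt), threshold_large)
  rare <- is_rare(df, maf_threshold)
  cons <- conservation_consensus(df$gerp, df$phylop)
  path <- pathogenicity_consensus(df$sift, df$lrt, df$polyphen2, df$mutation_taster)
  el <- !df$reported & df$in_monogenic_gene & rare
  tier <- rep(NA_integer_, nrow(df))
  rationale <- rep("excluded:reported_or_common_or_not_monogenic", nrow(df))
  tier[el] <- 4L
  rationale[el] <- "novel;rare;monogenic_gene"
  hit <- el & df$effect == "MISSENSE" & path
  tier[hit] <- 3L
  rationale[hit] <- "novel;rare;missense;pathogenicity_consensus"
  hit <- el & ((df$effect == "MISSENSE" & cons) | df$effect == "NONFRAMESHIFT_INDEL")
  tier[hit] <- 2L
  rationale[hit] <- ifelse(df$effect[hit] == "NONFRAMESHIFT_INDEL",
                           "novel;rare;nonframeshift_indel",
                           "novel;rare;missense;conservation_consensus")
  hit <- el & lof
  tier[hit] <- 1L
  rationale[hit] <- "novel;rare;lof"
  tibble(track = "NOVEL", tier = tier, rationale = rationale)
}

#' Assign tiers on both tracks
#'
#' @inheritParams tier_reported
#' @return long tibble: the annotated columns plus `track`, `tier`
#'   (1-4, `NA` = excluded from that track), and `rationale`; two rows per
#'   input variant (one per track).
#' @export
assign_tiers <- function(df, maf_threshold = 0.01, threshold_large = 50) {
  rep_t <- tier_reported(df, maf_threshold, threshold_large)
  nov_t <- tier_novel(df, maf_threshold, threshold_large)
  bind_rows(
    bind_cols(df, rep_t),
    bind_cols(df, nov_t)
  )
}

#' Retained review set (tiers 1-3)
#' @param tiers output of [assign_tiers()].
#' @export
retained_tiers <- function(tiers) {
  filter(tiers, !is.na(.data$tier), .data$tier <= 3L)
}

#' Local-cohort frequency filter
#'
#' Removes variants whose allele frequency in the local sequencing cohort is
#' at or above `cutoff` (default 0.25: variants under 25% local frequency are
#' retained). Variants absent from the local table are retained — absence is
#' not evidence of commonness.
#'
#' @param df tibble with a `local_af` column.
#' @param cutoff removal threshold (default 0.25).
#' @export
local_cohort_filter <- function(df, cutoff = 0.25) {
  if (!"local_af" %in% names(df)) return(df)
  filter(df, is.na(.data$local_af) | .data$local_af < cutoff)
}

#' Restrict variants to a gene set
#'
#' Keeps variants whose gene symbol is in `gene_set`. For female samples,
#' Y-chromosome variants are additionally dropped (disease associations on Y
#' cannot apply).
#'
#' @param df annotated tibble with `gene` and `chrom` columns.
#' @param gene_set non-empty character vector of gene symbols.
#' @param sample_sex `"unknown"`, `"female"`, or `"male"`.
#' @export
restrict_to_genes <- function(df, gene_set, sample_sex = c("unknown", "female", "male")) {
  sample_sex <- match.arg(sample_sex)
  if (length(gene_set) == 0) abort("gene_set must be non-empty")
  out <- filter(df, !is.na(.data$gene), .data$gene %in% gene_set)
  if (sample_sex == "female") {
    out <- filter(out, !.data$chrom %in% c("Y", "chrY"))
  }
  out
}

#' End-to-end prioritization of an annotated variant table
#'
#' Gene-set restriction, two-track tiering, retention of tiers 1-3, and the
#' local-cohort filter, in that order.
#'
#' @param annotated output of [annotate_variants()].
#' @param gene_set gene symbols to restrict to (`NULL` = no restriction).
#' @param sample_sex passed to [restrict_to_genes()].
#' @param maf_threshold,threshold_large tiering parameters.
#' @param local_af_cutoff passed to [local_cohort_filter()].
#' @return retained tier-1..3 assignments with rationale.
#' @export
prioritize_variants <- function(annotated, gene_set = NULL,
                                sample_sex = "unknown",
                                maf_threshold = 0.01, threshold_large = 50,
                                local_af_cutoff = 0.25) {
  df <- annotated
  if (!is.null(gene_set)) df <- restrict_to_genes(df, gene_set, sample_sex)
  tiers <- assign_tiers(df, maf_threshold, threshold_large)
  local_cohort_filter(retained_tiers(tiers), local_af_cutoff)
}

#' Tier counts per track
#' @param tiers output of [assign_tiers()] or [prioritize_variants()].
#' @return tibble `track, tier, n`.
#' @export
tier_summary <- function(tiers) {
  tiers %>%
    filter(!is.na(.data$tier)) %>%
    count(.data$track, .data$tier, name = "n") %>%
    arrange(.data$track, .data$tier)
}
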