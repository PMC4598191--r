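# Annotation joins and the derived predicates (loss of function, rarity,
# conservation consensus, pathogenicity consensus) that drive tiering.
#
# Missing-data semantics everywhere here: NA means "absent from the source",
# which is evidence of nothing. It is never coerced to zero, never counts as
# a pathogenicity vote, and fails the conservation consensus; only the rarity
# filter treats a fully absent frequency profile as rare (a variant seen in
# no survey is, by definition, not common).

DAMAGING_VOTES <- list(
  sift = "Damaging",
  lrt = "Deleterious",
  polyphen2 = c("Probably damaging", "Possibly damaging"),
  mutation_taster = c("Disease causing automatic", "Disease causing")
)
BENIGN_VOCAB <- list(
  sift = "Tolerated",
  lrt = c("Neutral", "Unknown"),
  polyphen2 = "Benign",
  mutation_taster = c("Polymorphism", "Polymorphism automatic")
)

#' Join variants to the annotation database and gene model
#'
#' Adds, per variant: `effect`/`gene`/`transcript` from [classify_effect()];
#' one `maf_<source>` column per population survey (see [FREQ_SOURCES]);
#' `local_af`; the score columns `gerp, phylop, sift, lrt, polyphen2,
#' mutation_taster`; and the flags `reported` (disease-mutation catalog
#' membership, with `reported_effect`) and `in_monogenic_gene`. Every input
#' row is emitted exactly once; absence from a table yields `NA`.
#'
#' @param df tibble with `chrom, pos, ref, alt` (a sites table or a long
#'   calls table).
#' @param db an [annotation_db()].
#' @param gene_model a [gene_model()]; when `NULL`, the input must already
#'   carry `effect` and `gene` columns.
#' @param large_indel passed to [classify_effect()].
#' @return annotated tibble.
#' @export
annotate_variants <- function(df, db, gene_model = NULL, large_indel = 50) {
  if (!"key" %in% names(df)) {
    df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  }
  if (!is.null(gene_model)) {
    df <- classify_effect(df, gene_model, large_indel = large_indel)
  } else if (!all(c("effect", "gene") %in% names(df))) {
    abort("without a gene_model, input must carry `effect` and `gene` columns")
  }
  freq_wide <- db$frequency %>%
    distinct(.data$key, .data$source, .data$maf) %>%
    tidyr::pivot_wider(names_from = "source", values_from = "maf",
                       names_prefix = "maf_")
  for (src in FREQ_SOURCES) {
    col <- paste0("maf_", src)
    if (!col %in% names(freq_wide)) freq_wide[[col]] <- NA_real_
  }
  df <- left_join(df, freq_wide[, c("key", paste0("maf_", FREQ_SOURCES))], by = "key")
  score_cols <- c("gerp", "phylop", "sift", "lrt", "polyphen2", "mutation_taster")
  df <- left_join(df, distinct(db$scores[, c("key", score_cols)], .data$key, .keep_all = TRUE),
                  by = "key")
  rep_tbl <- distinct(db$reported[, c("key", "reported_effect")], .data$key, .keep_all = TRUE)
  df <- left_join(df, rep_tbl, by = "key")
  df$reported <- !is.na(df$reported_effect)
  monogenic <- db$genes$gene[as.logical(db$genes$monogenic_flag)]
  df$in_monogenic_gene <- !is.na(df$gene) & df$gene %in% monogenic
  if (!is.null(db$local)) {
    loc <- distinct(db$local[, c("key", "af")], .data$key, .keep_all = TRUE)
    names(loc)[names(loc) == "af"] <- "local_af"
    df <- left_join(df, loc, by = "key")
  } else {
    df$local_af <- NA_real_
  }
  df
}

#' Loss-of-function predicate
#'
#' TRUE for splice-dinucleotide, nonsense, nonstop, frameshift, and large
#' in-frame coding indels (length at least `threshold_large`, default 50 bp).
#'
#' @param effect effect class vector.
#' @param indel_length absolute ref/alt length difference (0 for SNVs).
#' @param threshold_large large-indel size threshold in bp.
#' @return logical vector.
#' @export
is_lof <- function(effect, indel_length = 0L, threshold_large = 50) {
  effect %in% LOF_CLASSES |
    (effect == "NONFRAMESHIFT_INDEL" & indel_length >= threshold_large)
}

#' Rarity predicate over multi-source allele frequencies
#'
#' A variant is rare when its MAF is no greater than `maf_threshold` in every
#' population survey where it has been observed; a variant absent from all
#' surveys (novel) is rare. Equivalently: the maximum over present sources is
#' at most the threshold.
#'
#' @param df annotated tibble carrying the `maf_<source>` columns.
#' @param maf_threshold default 0.01 (1%).
#' @return logical vector.
#' @export
is_rare <- function(df, maf_threshold = 0.01) {
  cols <- paste0("maf_", FREQ_SOURCES)
  cols <- cols[cols %in% names(df)]
  if (length(cols) == 0) return(rep(TRUE, nrow(df)))
  m <- as.matrix(df[, cols])
  worst <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  is.infinite(worst) | worst <= maf_threshold
}

#' Evolutionary conservation consensus
#'
#' TRUE only when both scores are present and both exceed their thresholds
#' strictly: GERP++ > 2 and rescaled PhyloP > 0.95. A missing score fails
#' (no evidence is not evidence).
#'
#' @param gerp,phylop numeric vectors (NA = absent).
#' @return logical vector.
#' @export
conservation_consensus <- function(gerp, phylop) {
  !is.na(gerp) & gerp > 2 & !is.na(phylop) & phylop > 0.95
}

#' Pathogenicity-prediction consensus
#'
#' Counts damaging votes across four algorithms — SIFT "Damaging"; LRT
#' "Deleterious"; PolyPhen2 "Probably damaging" or "Possibly damaging";
#' MutationTaster "Disease causing automatic" or "Disease causing" — and
#' returns TRUE at three or more votes. Absent predictions do not vote; a
#' categorical value outside an algorithm's vocabulary triggers a warning and
#' does not vote.
#'
#' @param sift,lrt,polyphen2,mutation_taster character vectors.
#' @param min_votes vote threshold (default 3).
#' @return logical vector.
#' @export
pathogenicity_consensus <- function(sift, lrt, polyphen2, mutation_taster,
                                    min_votes = 3) {
  algs <- list(sift = sift, lrt = lrt, polyphen2 = polyphen2,
               mutation_taster = mutation_taster)
  votes <- rep(0L, length(sift))
  for (a in names(algs)) {
    x <- algs[[a]]
    known <- c(DAMAGING_VOTES[[a]], BENIGN_VOCAB[[a]])
    unknown <- !is.na(x) & !x %in% known
    if (any(unknown)) {
      warn(paste0("unknown ", a, " value(s) treated as non-votes: ",
                  paste(unique(x[unknown]), collapse = ", ")))
    }
    votes <- votes + as.integer(!is.na(x) & x %in% DAMAGING_VOTES[[a]])
  }
  votes >= min_votes
}
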