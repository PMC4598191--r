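# Seeded generators for every input the pipeline consumes, each a pure
# function of its spec and seed, with ground-truth manifests sufficient to
# compute the expected pipeline outputs independently.

# Trio genotype configurations by symbol, written as father/mother/child
# allele pairs. GOOD-region background MIAs deliberately avoid the de novo
# and hemizygosity genotype patterns so that the truth manifest alone
# determines the expected candidate lists.
CONSISTENT_CONFIGS <- list(
  list(f = c(0L, 1L), m = c(0L, 0L), c = c(0L, 0L)),
  list(f = c(0L, 1L), m = c(0L, 0L), c = c(0L, 1L)),
  list(f = c(0L, 0L), m = c(0L, 1L), c = c(0L, 0L)),
  list(f = c(0L, 0L), m = c(0L, 1L), c = c(0L, 1L)),
  list(f = c(1L, 1L), m = c(0L, 0L), c = c(0L, 1L)),
  list(f = c(0L, 0L), m = c(1L, 1L), c = c(0L, 1L)),
  list(f = c(1L, 1L), m = c(0L, 1L), c = c(0L, 1L)),
  list(f = c(0L, 1L), m = c(1L, 1L), c = c(1L, 1L)),
  list(f = c(1L, 1L), m = c(0L, 1L), c = c(1L, 1L)),
  list(f = c(0L, 1L), m = c(0L, 1L), c = c(0L, 0L)),
  list(f = c(1L, 1L), m = c(1L, 1L), c = c(1L, 1L))
)
GOOD_MIA_CONFIGS <- list(
  list(f = c(0L, 0L), m = c(1L, 1L), c = c(0L, 0L)),
  list(f = c(1L, 1L), m = c(0L, 0L), c = c(0L, 0L)),
  list(f = c(1L, 1L), m = c(1L, 1L), c = c(0L, 0L)),
  list(f = c(1L, 1L), m = c(1L, 1L), c = c(0L, 1L)),
  list(f = c(0L, 1L), m = c(1L, 1L), c = c(0L, 0L))
)
ARTIFACT_MIA_CONFIGS <- c(GOOD_MIA_CONFIGS, list(
  list(f = c(0L, 0L), m = c(0L, 0L), c = c(0L, 1L)),  # de novo pattern
  list(f = c(0L, 1L), m = c(0L, 0L), c = c(1L, 1L))   # hemizygous pattern
))
ALLHET_CONFIG <- list(f = c(0L, 1L), m = c(0L, 1L), c = c(0L, 1L))

#' Specification for a simulated trio
#'
#' The defaults describe the study conditions the package is validated under:
#' two autosomes carried as alternating planted segments (good data with one
#' reference-compression and one MIA-rich tract of 80 sites each), mean
#' marker spacing 3 kb, symbol emissions identical to the default HMM
#' emissions, and a handful of planted candidate events of each mode in
#' good-data regions plus de-novo-pattern artifacts inside the MIA-rich
#' tract.
#'
#' @param seed integer master seed.
#' @param plan tibble `chrom, state, n_sites`: consecutive planted segments.
#' @param mean_spacing mean inter-marker distance in bp.
#' @param emissions 3x3 symbol emission matrix per state (default: the
#'   [hmm_params()] defaults, so simulation matches the decoding model).
#' @param n_de_novo,n_compound_het,n_rare_hom,n_hemizygous,n_ad planted event
#'   counts.
#' @param n_artifact_events de-novo-pattern sites planted inside MIA_RICH
#'   segments (tagged artifact in the manifest; must never be reported).
#' @param rare_maf,common_maf survey frequencies assigned to planted-rare and
#'   background-common variants.
#' @param novel_rate fraction of background variants absent from all surveys.
#' @param gene_tile_bp width of the gene tiling used for gene-level modes.
#' @return object of class `trio_sim_spec`.
#' @export
trio_sim_spec <- function(seed = 1,
                          plan = tibble(
                            chrom = c("1", "1", "1", "1", "1", "2"),
                            state = c("GOOD", "COMPRESSION", "GOOD", "MIA_RICH", "GOOD", "GOOD"),
                            n_sites = c(400L, 80L, 400L, 80L, 400L, 400L)
                          ),
                          mean_spacing = 3000,
                          emissions = NULL,
                          n_de_novo = 3L, n_compound_het = 2L, n_rare_hom = 2L,
                          n_hemizygous = 1L, n_ad = 2L, n_artifact_events = 3L,
                          rare_maf = 0.001, common_maf = 0.2,
                          novel_rate = 0.05, gene_tile_bp = 100000L) {
  emissions <- emissions %||% hmm_params()$emissions
  stopifnot(all(plan$state %in% HMM_STATES), all(plan$n_sites > 0))
  structure(
    list(seed = seed, plan = plan, mean_spacing = mean_spacing,
         emissions = emissions,
         n_de_novo = n_de_novo, n_compound_het = n_compound_het,
         n_rare_hom = n_rare_hom, n_hemizygous = n_hemizygous, n_ad = n_ad,
         n_artifact_events = n_artifact_events,
         rare_maf = rare_maf, common_maf = common_maf,
         novel_rate = novel_rate, gene_tile_bp = gene_tile_bp),
    class = "trio_sim_spec"
  )
}

#' Simulate a father-mother-child trio with planted truth
#'
#' Generates per-site trio genotypes whose symbols follow the planted
#' segment's emission distribution, then overwrites selected good-data sites
#' with planted candidate events (and MIA-rich sites with tagged artifact
#' events). The output is a pure function of the spec: the same spec gives
#' identical tibbles, and writing with [write_trio_sim()] gives
#' byte-identical files.
#'
#' @param spec a [trio_sim_spec()].
#' @return list of class `trio_sim`: `calls` (long calls tibble, samples
#'   FATHER/MOTHER/CHILD), `sites` (per-site truth: `chrom, pos, key,
#'   true_state, symbol, planted`), `manifest` (planted events: `type, chrom,
#'   pos, key, gene, partner_key, phase, artifact`), `segments_truth`,
#'   `frequencies` (long survey table), `gene_intervals`, `deletions`,
#'   `disease_genes`, `spec`.
#' @export
simulate_trio <- function(spec) {
  stopifnot(inherits(spec, "trio_sim_spec"))
  plan <- spec$plan

  # site positions per chromosome
  sites <- local_rng(derive_seed(spec$seed, "segments"), {
    out <- list()
    for (ch in unique(plan$chrom)) {
      n <- sum(plan$n_sites[plan$chrom == ch])
      gaps <- pmax(1L, round(stats::rexp(n, rate = 1 / spec$mean_spacing)))
      pos <- cumsum(gaps) + 10000L
      states <- rep(plan$state[plan$chrom == ch], plan$n_sites[plan$chrom == ch])
      out[[ch]] <- tibble(chrom = ch, pos = as.integer(pos), true_state = states)
    }
    bind_rows(out)
  })

  # symbols from the planted state's emission row
  sites <- local_rng(derive_seed(spec$seed, "genotypes"), {
    sym <- character(nrow(sites))
    for (s in HMM_STATES) {
      idx <- which(sites$true_state == s)
      sym[idx] <- sample(HMM_SYMBOLS, length(idx), replace = TRUE,
                         prob = spec$emissions[s, ])
    }
    sites$symbol <- sym
    sites
  })

  # genotype configuration per site
  pick_cfg <- function(symbol, state) {
    if (symbol == "ALLHET") return(ALLHET_CONFIG)
    if (symbol == "CONSISTENT") {
      return(CONSISTENT_CONFIGS[[sample.int(length(CONSISTENT_CONFIGS), 1)]])
    }
    pool <- if (state == "GOOD") GOOD_MIA_CONFIGS else ARTIFACT_MIA_CONFIGS
    pool[[sample.int(length(pool), 1)]]
  }
  cfgs <- local_rng(derive_seed(spec$seed, "noise"), {
    purrr::map2(sites$symbol, sites$true_state, pick_cfg)
  })

  # gene tiling
  gene_intervals <- sites %>%
    group_by(.data$chrom) %>%
    summarise(max_pos = max(.data$pos), .groups = "drop") %>%
    purrr::pmap(function(chrom, max_pos) {
      starts <- seq(0L, max_pos, by = spec$gene_tile_bp)
      tibble(gene = sprintf("G%s_%03d", chrom, seq_along(starts)),
             chrom = chrom, start = starts,
             end = starts + spec$gene_tile_bp)
    }) %>% bind_rows()

  # planted events ------------------------------------------------------------
  # events go into segment interiors (>= 5 sites from every planted state
  # change): segment boundaries are only estimable to within about one marker
  # spacing, so edge sites carry no recoverable event guarantee
  margin <- 5L
  sites$interior <- unlist(lapply(split(sites$true_state, sites$chrom)[unique(sites$chrom)],
    function(st) {
      r <- rle(st)
      unlist(lapply(r$lengths, function(L) {
        k <- seq_len(L)
        k > margin & k <= L - margin
      }))
    }))
  sites$planted <- NA_character_
  manifest <- list()
  deletions <- tibble(chrom = character(), start = integer(), end = integer())
  ev <- local_rng(derive_seed(spec$seed, "events"), {
    good_idx <- which(sites$true_state == "GOOD" & sites$interior)
    free <- sample(good_idx)  # random order, consumed as events are planted
    take <- function(n) {
      if (n <= 0) return(integer(0))
      idx <- free[seq_len(n)]
      free <<- free[-seq_len(n)]
      idx
    }
    man <- list()
    set_cfg <- function(i, f, m, c) cfgs[[i]] <<- list(f = f, m = m, c = c)

    for (i in take(spec$n_de_novo)) {
      set_cfg(i, c(0L, 0L), c(0L, 0L), c(0L, 1L))
      sites$planted[i] <- "de_novo"
      man[[length(man) + 1]] <- tibble(type = "de_novo", chrom = sites$chrom[i],
                                       pos = sites$pos[i], artifact = FALSE)
    }
    # compound het: partner = nearest later GOOD site in the same gene tile
    site_gene <- assign_genes(sites, gene_intervals)$gene
    ch_planted <- 0L
    k <- 1L
    while (ch_planted < spec$n_compound_het && k <= length(free)) {
      i <- free[k]
      partner <- free[free != i &
                        sites$chrom[free] == sites$chrom[i] &
                        site_gene[free] == site_gene[i]]
      if (length(partner) == 0) { k <- k + 1L; next }
      j <- partner[1]
      free <- setdiff(free, c(i, j))
      set_cfg(i, c(0L, 1L), c(0L, 0L), c(0L, 1L))  # paternal, rare
      set_cfg(j, c(0L, 0L), c(0L, 1L), c(0L, 1L))  # maternal, common
      sites$planted[i] <- "compound_het_rare"
      sites$planted[j] <- "compound_het_common"
      man[[length(man) + 1]] <- tibble(
        type = "compound_het", chrom = sites$chrom[i], pos = sites$pos[i],
        partner_pos = sites$pos[j], gene = site_gene[i],
        phase = "TRANS_CONFIRMED", artifact = FALSE
      )
      ch_planted <- ch_planted + 1L
    }
    for (i in take(spec$n_rare_hom)) {
      set_cfg(i, c(0L, 1L), c(0L, 1L), c(1L, 1L))
      sites$planted[i] <- "rare_homozygous"
      man[[length(man) + 1]] <- tibble(type = "rare_homozygous",
                                       chrom = sites$chrom[i],
                                       pos = sites$pos[i], artifact = FALSE)
    }
    for (i in take(spec$n_hemizygous)) {
      set_cfg(i, c(0L, 1L), c(0L, 0L), c(1L, 1L))
      sites$planted[i] <- "hemizygous"
      deletions <- bind_rows(deletions, tibble(
        chrom = sites$chrom[i], start = sites$pos[i] - 100L,
        end = sites$pos[i] + 100L
      ))
      man[[length(man) + 1]] <- tibble(type = "hemizygous",
                                       chrom = sites$chrom[i],
                                       pos = sites$pos[i], artifact = FALSE)
    }
    for (i in take(spec$n_ad)) {
      set_cfg(i, c(0L, 1L), c(0L, 0L), c(0L, 1L))
      sites$planted[i] <- "ad_reduced_penetrance"
      man[[length(man) + 1]] <- tibble(type = "ad_reduced_penetrance",
                                       chrom = sites$chrom[i],
                                       pos = sites$pos[i],
                                       gene = site_gene[i], artifact = FALSE)
    }
    # artifact events: de novo genotype pattern inside MIA_RICH
    mia_idx <- which(sites$true_state == "MIA_RICH" & sites$interior)
    if (spec$n_artifact_events > 0 && length(mia_idx) > 0) {
      for (i in sample(mia_idx, min(spec$n_artifact_events, length(mia_idx)))) {
        set_cfg(i, c(0L, 0L), c(0L, 0L), c(0L, 1L))
        sites$planted[i] <- "artifact_de_novo"
        man[[length(man) + 1]] <- tibble(type = "de_novo",
                                         chrom = sites$chrom[i],
                                         pos = sites$pos[i], artifact = TRUE)
      }
    }
    man
  })
  manifest <- bind_rows(ev)

  # symbols after planting (events overwrite genotypes, so re-derive)
  sym2 <- vapply(cfgs, function(cf) {
    if (!trio_consistent(cf$f[1], cf$f[2], cf$m[1], cf$m[2], cf$c[1], cf$c[2])) "MIA"
    else if (cf$f[1] != cf$f[2] && cf$m[1] != cf$m[2] && cf$c[1] != cf$c[2]) "ALLHET"
    else "CONSISTENT"
  }, character(1))
  sites$symbol <- sym2

  # alleles and calls tibble
  calls <- local_rng(derive_seed(spec$seed, "frequencies"), {
    ref <- sample(c("A", "C", "G", "T"), nrow(sites), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    sites$ref <- ref
    sites$alt <- alt
    sites$key <- paste(sites$chrom, sites$pos, ref, alt, sep = ":")
    dp <- sample(30:60, nrow(sites) * 3, replace = TRUE)
    gq <- sample(60:99, nrow(sites) * 3, replace = TRUE)
    roles <- c("FATHER", "MOTHER", "CHILD")
    role_gt <- list(
      FATHER = purrr::map(cfgs, "f"),
      MOTHER = purrr::map(cfgs, "m"),
      CHILD = purrr::map(cfgs, "c")
    )
    out <- purrr::imap(role_gt, function(gts, role) {
      tibble(
        chrom = sites$chrom, pos = sites$pos, id = ".",
        ref = sites$ref, alt = sites$alt, qual = 100,
        filter = "PASS", key = sites$key, sample = role,
        a1 = purrr::map_int(gts, 1), a2 = purrr::map_int(gts, 2),
        phased = FALSE, dp = NA_real_, gq = NA_real_, status = "CALLED"
      )
    })
    out <- bind_rows(out)
    out$dp <- as.numeric(dp)
    out$gq <- as.numeric(gq)
    arrange(out, .data$chrom, .data$pos, match(.data$sample, roles))
  })

  # survey frequencies: planted-rare sites rare everywhere they appear,
  # background either common or absent (novel)
  frequencies <- local_rng(derive_seed(spec$seed, "annotation"), {
    rare_sites <- !is.na(sites$planted) &
      sites$planted %in% c("de_novo", "compound_het_rare", "rare_homozygous",
                           "hemizygous", "ad_reduced_penetrance",
                           "artifact_de_novo")
    common_partner <- !is.na(sites$planted) & sites$planted == "compound_het_common"
    novel <- !rare_sites & !common_partner & runif(nrow(sites)) < spec$novel_rate
    maf <- ifelse(rare_sites, spec$rare_maf,
                  ifelse(common_partner, spec$common_maf,
                         runif(nrow(sites), 0.05, 0.5)))
    keep <- !novel
    bind_rows(
      tibble(chrom = sites$chrom[keep], pos = sites$pos[keep],
             ref = sites$ref[keep], alt = sites$alt[keep],
             source = "kg_global", maf = maf[keep]),
      tibble(chrom = sites$chrom[keep], pos = sites$pos[keep],
             ref = sites$ref[keep], alt = sites$alt[keep],
             source = "exac", maf = maf[keep])
    )
  })

  # truth segments with the same midpoint boundary convention as the decoder
  segments_truth <- sites %>%
    group_by(.data$chrom) %>%
    group_modify(function(df, grp) {
      r <- rle(df$true_state)
      ends_i <- cumsum(r$lengths)
      starts_i <- c(1L, head(ends_i, -1) + 1L)
      prev_pos <- df$pos[pmax(starts_i - 1L, 1L)]
      tibble(
        start = as.integer(ifelse(starts_i == 1L, df$pos[1] - 1L,
                                  (prev_pos + df$pos[starts_i]) %/% 2L)),
        end = as.integer(ifelse(ends_i == nrow(df), df$pos[nrow(df)],
                                (df$pos[ends_i] + df$pos[pmin(ends_i + 1L, nrow(df))]) %/% 2L)),
        state = r$values, n_sites = r$lengths
      )
    }) %>% ungroup()

  # manifest keys and genes
  if (nrow(manifest) > 0) {
    mk <- match(paste(manifest$chrom, manifest$pos), paste(sites$chrom, sites$pos))
    manifest$key <- sites$key[mk]
    if ("partner_pos" %in% names(manifest)) {
      pk <- match(paste(manifest$chrom, manifest$partner_pos),
                  paste(sites$chrom, sites$pos))
      manifest$partner_key <- sites$key[pk]
    }
    if (!"gene" %in% names(manifest)) manifest$gene <- NA_character_
  }
  disease_genes <- if (nrow(manifest) > 0) {
    unique(stats::na.omit(manifest$gene[manifest$type == "ad_reduced_penetrance"]))
  } else {
    manifest <- tibble(type = character(), chrom = character(), pos = integer(),
                       gene = character(), key = character(), artifact = logical())
    character(0)
  }

  structure(
    list(calls = calls, sites = sites, manifest = manifest,
         segments_truth = segments_truth, frequencies = frequencies,
         gene_intervals = gene_intervals, deletions = deletions,
         disease_genes = disease_genes, spec = spec,
         samples = c(father = "FATHER", mother = "MOTHER", child = "CHILD")),
    class = "trio_sim"
  )
}

#' Annotate a trio-wide table with the simulation's gene and frequency truth
#'
#' Joins the gene tiling and the survey frequency table of a [simulate_trio()]
#' result onto a [trio_wide()] table, producing the columns the candidate
#' finders consume.
#' @param tw trio-wide tibble.
#' @param sim a `trio_sim`.
#' @export
annotate_trio_sim <- function(tw, sim) {
  tw <- assign_genes(tw, sim$gene_intervals)
  fw <- sim$frequencies %>%
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    distinct(.data$key, .data$source, .data$maf) %>%
    tidyr::pivot_wider(names_from = "source", values_from = "maf",
                       names_prefix = "maf_")
  left_join(tw, fw, by = "key")
}

#' Write a simulated trio to disk
#'
#' VCF (3 samples), truth-segments BED, deletions BED, frequency TSV, gene
#' intervals TSV, and the manifest TSV, all plain text.
#' @param sim a `trio_sim`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_trio_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "trio.vcf"),
    segments = file.path(dir, "segments_truth.bed"),
    deletions = file.path(dir, "deletions.bed"),
    frequencies = file.path(dir, "frequencies.tsv"),
    genes = file.path(dir, "gene_intervals.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_vcf(sim$calls, paths["vcf"])
  write_bed(sim$segments_truth, paths["segments"], name_col = "state")
  if (nrow(sim$deletions) > 0) {
    write_bed(sim$deletions, paths["deletions"])
  } else {
    writeLines(character(0), paths["deletions"])
  }
  readr::write_tsv(sim$frequencies, paths["frequencies"])
  readr::write_tsv(sim$gene_intervals, paths["genes"])
  readr::write_tsv(sim$manifest, paths["manifest"])
  paths
}

# Star-allele fixture ----------------------------------------------------------

#' Random star-allele fixture with known true diplotype
#'
#' Draws `n_alleles` pairwise-distinct allele vectors over `n_positions`
#' defining positions (always including the all-reference `*1`), samples a
#' true diplotype, and derives the sample's genotypes from it. Optionally
#' masks positions (status LOW_CONFIDENCE) for ambiguity tests.
#'
#' @param seed integer seed.
#' @param n_alleles number of star alleles (must be at most
#'   `2^n_positions`).
#' @param n_positions number of defining positions.
#' @param mask integer indices of defining positions to mask.
#' @param disjoint give every non-reference allele its own disjoint block of
#'   defining positions. Such definition sets are structurally identifiable:
#'   a fully-called genotype always resolves to exactly one diplotype. With
#'   `disjoint = FALSE` (default) alleles are arbitrary distinct vectors, and
#'   an unphased genotype may legitimately be ambiguous even when fully
#'   called (several recombinations can each perfect-match a defined pair).
#' @return list: `definitions` (long tibble), `genotypes` (calls-like tibble,
#'   sample `"S1"`), `truth` (sorted character pair), `gene`, `allele_vectors`
#'   (logical matrix, TRUE = alternate).
#' @export
make_star_fixture <- function(seed, n_alleles = 4, n_positions = 5,
                              mask = integer(0), disjoint = FALSE) {
  if (n_alleles > 2^n_positions) {
    abort("n_alleles must not exceed 2^n_positions (distinct vectors infeasible)")
  }
  if (disjoint && n_alleles - 1 > n_positions) {
    abort("disjoint definitions need at least one position per non-reference allele")
  }
  local_rng(derive_seed(seed, "star"), {
    if (disjoint) {
      owner <- sort(rep_len(seq_len(n_alleles - 1), n_positions))
      vecs <- rbind(rep(FALSE, n_positions),
                    t(vapply(seq_len(n_alleles - 1), function(i) owner == i,
                             logical(n_positions))))
    } else {
      codes <- c(0L, sample(seq_len(2^n_positions - 1), n_alleles - 1))
      vecs <- t(vapply(codes, function(cd) {
        as.logical(bitwAnd(bitwShiftR(cd, 0:(n_positions - 1)), 1L))
      }, logical(n_positions)))
    }
    allele_names <- paste0("*", seq_len(n_alleles))
    rownames(vecs) <- allele_names
    pos <- 5000L + 500L * (seq_len(n_positions) - 1L)
    ref <- sample(c("A", "C", "G", "T"), n_positions, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    defs <- purrr::map(seq_len(n_alleles), function(i) {
      j <- which(vecs[i, ])
      if (length(j) == 0) return(NULL)
      tibble(gene = "STARG1", allele = allele_names[i], chrom = "10",
             pos = pos[j], ref = ref[j], alt = alt[j])
    }) %>% bind_rows()
    truth <- sort(sample(allele_names, 2, replace = TRUE))
    n_alt <- as.integer(vecs[truth[1], ]) + as.integer(vecs[truth[2], ])
    a1 <- as.integer(n_alt >= 1)
    a2 <- as.integer(n_alt == 2)
    status <- rep("CALLED", n_positions)
    gq <- rep(99, n_positions)
    status[mask] <- "LOW_CONFIDENCE"
    gq[mask] <- 5
    genotypes <- tibble(
      chrom = "10", pos = pos, id = ".", ref = ref, alt = alt,
      qual = 100, filter = "PASS",
      key = paste("10", pos, ref, alt, sep = ":"),
      sample = "S1", a1 = a1, a2 = a2, phased = FALSE,
      dp = 50, gq = gq, status = status
    )
    list(definitions = defs, genotypes = genotypes, truth = truth,
         gene = "STARG1", allele_vectors = vecs)
  })
}

# Annotation fixture -----------------------------------------------------------

#' Annotation fixture over the toy genome
#'
#' Variants engineered against [toy_gene_model()] to realize every effect
#' class (nonsense, nonstop, splice, frameshift / in-frame / large indels,
#' missense, synonymous, UTR, intronic, intergenic, and minus-strand probes),
#' together with annotation tables that include threshold boundary probes
#' (MAF exactly 0.01, GERP exactly 2.0, rescaled PhyloP exactly 0.95).
#' Deterministic for a given seed.
#'
#' @param seed integer seed.
#' @return list: `gene_model`, `variants` (tibble with an
#'   `expected_effect` column), `db` (an [annotation_db()]).
#' @export
make_annotation_fixture <- function(seed = 1) {
  gm <- toy_gene_model()
  base_at <- function(chrom, pos) genome_bases(gm$genome, chrom, pos)
  seg <- function(chrom, from, to) substr(gm$genome[[chrom]], from, to)
  v <- list()
  addv <- function(chrom, pos, ref, alt, expected) {
    v[[length(v) + 1]] <<- tibble(chrom = chrom, pos = as.integer(pos),
                                  ref = ref, alt = alt,
                                  expected_effect = expected)
  }
  # TOYG1 (+ strand): codon 2 is CAG (glutamine) at 1104-1106
  addv("1", 1104, "C", "T", "NONSENSE")      # CAG -> TAG
  addv("1", 1106, "G", "A", "SYNONYMOUS")    # CAG -> CAA
  addv("1", 1105, "A", "G", "MISSENSE")      # CAG -> CGG
  addv("1", 2599, "T", "C", "NONSTOP")       # TAA stop -> CAA
  addv("1", 1200, base_at("1", 1200), setdiff(c("A", "C"), base_at("1", 1200))[1],
       "SPLICE_DINUCLEOTIDE")                # donor +1 of exon 1
  addv("1", 1510, seg("1", 1510, 1511), base_at("1", 1510), "FRAMESHIFT_INDEL")
  addv("1", 1520, seg("1", 1520, 1523), base_at("1", 1520), "NONFRAMESHIFT_INDEL")
  addv("1", 1530, seg("1", 1530, 1590), base_at("1", 1530), "LARGE_CODING_INDEL")
  addv("1", 1050, base_at("1", 1050), setdiff(c("A", "C"), base_at("1", 1050))[1], "UTR")
  addv("1", 1300, base_at("1", 1300), setdiff(c("A", "C"), base_at("1", 1300))[1], "INTRONIC")
  addv("1", 50000, base_at("1", 50000), setdiff(c("A", "C"), base_at("1", 50000))[1], "INTERGENIC")
  # TOYG2 (- strand): transcript codon 2 spans genomic 11896..11894;
  # transcript C>T at its first base = genomic G>A at 11896 (CAG -> TAG)
  addv("2", 11896, "G", "A", "NONSENSE")
  addv("2", 11894, "C", "T", "SYNONYMOUS")   # transcript CAG -> CAA (G>A on tx)
  addv("2", 11895, "T", "C", "MISSENSE")     # transcript A>G: CAG -> CGG
  variants <- bind_rows(v)

  frequency <- local_rng(derive_seed(seed, "annotation"), {
    bind_rows(
      tibble(chrom = "1", pos = 1104L, ref = "C", alt = "T",
             source = "kg_global", maf = 0.30),                 # reported LOF, common
      tibble(chrom = "1", pos = 1105L, ref = "A", alt = "G",
             source = c("kg_global", "exac"), maf = c(0.001, 0.002)),
      tibble(chrom = "1", pos = 1106L, ref = "G", alt = "A",
             source = "exac", maf = 0.01),                      # boundary: rare
      tibble(chrom = "1", pos = 1520L, ref = seg("1", 1520, 1523),
             alt = base_at("1", 1520), source = "kg_global", maf = 0.005),
      tibble(chrom = "2", pos = 11895L, ref = "T", alt = "C",
             source = "cg69", maf = 0.04)                       # common by one source
    )
  })
  scores <- tibble(
    chrom = c("1", "1", "2", "2"),
    pos = c(1105L, 1106L, 11895L, 11896L),
    ref = c("A", "G", "T", "G"), alt = c("G", "A", "C", "A"),
    gerp = c(3.1, 2.0, 4.0, NA),        # 2.0 = strict-boundary probe
    phylop = c(0.97, 0.95, 0.99, NA),   # 0.95 = strict-boundary probe
    sift = c("Damaging", "Tolerated", "Damaging", NA),
    lrt = c("Deleterious", "Neutral", "Deleterious", NA),
    polyphen2 = c("Possibly damaging", "Benign", "Probably damaging", NA),
    mutation_taster = c("Polymorphism", "Polymorphism", "Disease causing", NA)
  )
  reported <- tibble(
    chrom = c("1", "1"), pos = c(1104L, 1106L),
    ref = c("C", "G"), alt = c("T", "A"),
    reported_effect = c("DM", "DM")
  )
  genes <- tibble(
    gene = c("TOYG1", "TOYG2", "TOYG3"),
    monogenic_flag = c(TRUE, TRUE, FALSE)
  )
  local <- tibble(
    chrom = c("1", "2"), pos = c(1104L, 11895L),
    ref = c("C", "T"), alt = c("T", "C"),
    af = c(0.40, 0.10)
  )
  list(gene_model = gm, variants = variants,
       db = annotation_db(frequency, scores, reported, genes, local))
}

#' Write the annotation fixture tables as TSV files
#' @param fix output of [make_annotation_fixture()].
#' @param dir output directory.
#' @return named vector of paths (`frequency, scores, reported, genes, local`).
#' @export
write_annotation_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db <- fix$db
  paths <- c(frequency = file.path(dir, "frequency.tsv"),
             scores = file.path(dir, "scores.tsv"),
             reported = file.path(dir, "reported.tsv"),
             genes = file.path(dir, "genes.tsv"),
             local = file.path(dir, "local.tsv"))
  drop_key <- function(df) df[, setdiff(names(df), "key")]
  readr::write_tsv(drop_key(db$frequency), paths["frequency"])
  readr::write_tsv(drop_key(db$scores), paths["scores"])
  readr::write_tsv(drop_key(db$reported), paths["reported"])
  readr::write_tsv(db$genes, paths["genes"])
  readr::write_tsv(drop_key(db$local), paths["local"])
  paths
}

#' Grid of annotated variants covering every tiering predicate combination
#'
#' Enumerates reported status, monogenic-gene membership, rarity (rare /
#' common / absent-from-all-surveys), effect class, conservation consensus,
#' and pathogenicity votes (0, 2, 3, 4), one synthetic annotated variant per
#' combination — the exhaustive truth table behind the tiering tests.
#'
#' @return annotated-shaped tibble with the generating factors as columns
#'   (`g_reported, g_monogenic, g_rarity, g_effect, g_cons, g_votes`).
#' @export
make_tier_grid <- function() {
  grid <- tidyr::expand_grid(
    g_reported = c(TRUE, FALSE),
    g_monogenic = c(TRUE, FALSE),
    g_rarity = c("rare", "common", "absent"),
    g_effect = c("NONSENSE", "FRAMESHIFT_INDEL", "MISSENSE",
                 "NONFRAMESHIFT_INDEL", "SYNONYMOUS", "INTRONIC"),
    g_cons = c(TRUE, FALSE),
    g_votes = c(0L, 2L, 3L, 4L)
  )
  n <- nrow(grid)
  vote_sets <- list(
    `0` = list(sift = "Tolerated", lrt = "Neutral", polyphen2 = "Benign",
               mutation_taster = "Polymorphism"),
    `2` = list(sift = "Damaging", lrt = "Deleterious", polyphen2 = "Benign",
               mutation_taster = "Polymorphism"),
    `3` = list(sift = "Damaging", lrt = "Deleterious",
               polyphen2 = "Possibly damaging", mutation_taster = "Polymorphism"),
    `4` = list(sift = "Damaging", lrt = "Deleterious",
               polyphen2 = "Probably damaging",
               mutation_taster = "Disease causing")
  )
  vs <- vote_sets[as.character(grid$g_votes)]
  tibble(
    chrom = "1", pos = 1000L + seq_len(n), ref = "A", alt = "T",
    key = paste("1", 1000L + seq_len(n), "A", "T", sep = ":"),
    effect = grid$g_effect,
    gene = ifelse(grid$g_monogenic, "MONO1", "OTHER1"),
    maf_hapmap_matched = NA_real_,
    maf_kg_superpop_matched = NA_real_,
    maf_kg_global = dplyr::case_when(
      grid$g_rarity == "rare" ~ 0.001,
      grid$g_rarity == "common" ~ 0.10,
      TRUE ~ NA_real_
    ),
    maf_kg_pilot_global = NA_real_,
    maf_cg69 = ifelse(grid$g_rarity == "rare", 0.005, NA_real_),
    maf_esp_global = NA_real_,
    maf_exac = NA_real_,
    gerp = ifelse(grid$g_cons, 3.5, 1.0),
    phylop = ifelse(grid$g_cons, 0.99, 0.50),
    sift = purrr::map_chr(vs, "sift"),
    lrt = purrr::map_chr(vs, "lrt"),
    polyphen2 = purrr::map_chr(vs, "polyphen2"),
    mutation_taster = purrr::map_chr(vs, "mutation_taster"),
    reported = grid$g_reported,
    reported_effect = ifelse(grid$g_reported, "DM", NA_character_),
    in_monogenic_gene = grid$g_monogenic,
    local_af = NA_real_,
    g_reported = grid$g_reported, g_monogenic = grid$g_monogenic,
    g_rarity = grid$g_rarity, g_effect = grid$g_effect,
    g_cons = grid$g_cons, g_votes = grid$g_votes
  )
}

#' Random annotated variants for oracle cross-checks
#'
#' Samples annotated-shaped variants with independent random predicates
#' (including absent scores and frequencies) for property tests against
#' independently coded decision tables.
#'
#' @param n number of variants.
#' @param seed integer seed.
#' @return annotated-shaped tibble.
#' @export
make_random_annotated <- function(n, seed = 1) {
  local_rng(derive_seed(seed, "annotation"), {
    maybe <- function(x, p_absent = 0.3) {
      ifelse(runif(n) < p_absent, NA, x)
    }
    effects <- sample(EFFECT_LEVELS, n, replace = TRUE)
    sift_v <- sample(c("Damaging", "Tolerated"), n, TRUE)
    lrt_v <- sample(c("Deleterious", "Neutral"), n, TRUE)
    pp_v <- sample(c("Probably damaging", "Possibly damaging", "Benign"), n, TRUE)
    mt_v <- sample(c("Disease causing automatic", "Disease causing",
                     "Polymorphism"), n, TRUE)
    maybe_chr <- function(x, p = 0.3) ifelse(runif(n) < p, NA_character_, x)
    tibble(
      chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
      key = paste("1", seq_len(n), "A", "G", sep = ":"),
      effect = effects, gene = sample(c("MONO1", "OTHER1"), n, TRUE),
      maf_hapmap_matched = maybe(runif(n, 0, 0.02)),
      maf_kg_superpop_matched = maybe(runif(n, 0, 0.3)),
      maf_kg_global = maybe(runif(n, 0, 0.05)),
      maf_kg_pilot_global = maybe(runif(n, 0, 0.05), 0.8),
      maf_cg69 = maybe(runif(n, 0, 0.5), 0.6),
      maf_esp_global = maybe(runif(n, 0, 0.02), 0.5),
      maf_exac = maybe(runif(n, 0, 0.02), 0.2),
      gerp = maybe(runif(n, -2, 6)),
      phylop = maybe(runif(n, 0, 1)),
      sift = maybe_chr(sift_v), lrt = maybe_chr(lrt_v),
      polyphen2 = maybe_chr(pp_v), mutation_taster = maybe_chr(mt_v),
      reported = runif(n) < 0.5,
      in_monogenic_gene = runif(n) < 0.5,
      local_af = maybe(runif(n), 0.5)
    ) %>% mutate(reported_effect = ifelse(.data$reported, "DM", NA_character_))
  })
}
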