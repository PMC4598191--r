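GOOD_SEG <- all_good_segments("1")
BAD_SEG <- tibble::tibble(chrom = "1", start = 0L, end = .Machine$integer.max,
                          state = "MIA_RICH", n_sites = 0L)

test_that("de novo finder requires confident hom-ref parents, het child, good region", {
  hit <- tw_row(f = c(0L, 0L), m = c(0L, 0L), cc = c(0L, 1L))
  expect_equal(nrow(find_de_novo(hit, GOOD_SEG)), 1)
  # identical genotypes inside an MIA-rich region are suppressed
  expect_equal(nrow(find_de_novo(hit, BAD_SEG)), 0)
  # parental NO_CALL disqualifies in strict mode, passes in lenient only if
  # the genotype is present
  nc <- tw_row(f = c(0L, 0L), m = c(0L, 0L), cc = c(0L, 1L), f_status = "NO_CALL")
  expect_equal(nrow(find_de_novo(nc, GOOD_SEG)), 0)
  lc <- tw_row(f = c(0L, 0L), m = c(0L, 0L), cc = c(0L, 1L),
               f_status = "LOW_CONFIDENCE")
  expect_equal(nrow(find_de_novo(lc, GOOD_SEG)), 0)
  expect_equal(nrow(find_de_novo(lc, GOOD_SEG, strict = FALSE)), 1)
  # carrier parent disqualifies
  carrier <- tw_row(f = c(0L, 1L), m = c(0L, 0L), cc = c(0L, 1L))
  expect_equal(nrow(find_de_novo(carrier, GOOD_SEG)), 0)
})

test_that("compound-het pairs classify phase like the spec examples", {
  g <- dplyr::bind_rows(
    tw_row(pos = 1000L, f = c(0L, 1L), m = c(0L, 0L), cc = c(0L, 1L),
           gene = "G1", maf = 0.001),                      # paternal only, rare
    tw_row(pos = 2000L, f = c(0L, 0L), m = c(0L, 1L), cc = c(0L, 1L),
           gene = "G1", maf = 0.2)                         # maternal only, common
  )
  out <- find_compound_het(g, GOOD_SEG)
  expect_equal(nrow(out), 1)
  expect_equal(out$phase, "TRANS_CONFIRMED")
  # both variants carried only by the father: provably cis, excluded
  cis <- dplyr::bind_rows(
    tw_row(pos = 1000L, f = c(0L, 1L), m = c(0L, 0L), cc = c(0L, 1L),
           gene = "G1", maf = 0.001),
    tw_row(pos = 2000L, f = c(0L, 1L), m = c(0L, 0L), cc = c(0L, 1L),
           gene = "G1", maf = 0.2)
  )
  expect_equal(nrow(find_compound_het(cis, GOOD_SEG)), 0)
  # both parents het at both sites: phase not excludable
  unk <- dplyr::bind_rows(
    tw_row(pos = 1000L, f = c(0L, 1L), m = c(0L, 1L), cc = c(0L, 1L),
           gene = "G1", maf = 0.001),
    tw_row(pos = 2000L, f = c(0L, 1L), m = c(0L, 1L), cc = c(0L, 1L),
           gene = "G1", maf = 0.2)
  )
  expect_equal(find_compound_het(unk, GOOD_SEG)$phase, "PHASE_UNKNOWN")
  # neither variant rare: pair not reported
  common <- dplyr::mutate(g, maf_kg_global = 0.3)
  expect_equal(nrow(find_compound_het(common, GOOD_SEG)), 0)
})

test_that("compound-het phase matches the transmission-assignment oracle on random fixtures", {
  withr::with_seed(77, {
    gts <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
    n_checked <- 0
    for (trial in 1:300) {
      v1 <- tw_row(pos = 1000L, f = gts[[sample(3, 1)]], m = gts[[sample(3, 1)]],
                   cc = c(0L, 1L), gene = "G1", maf = 0.001)
      v2 <- tw_row(pos = 2000L, f = gts[[sample(3, 1)]], m = gts[[sample(3, 1)]],
                   cc = c(0L, 1L), gene = "G1", maf = 0.3)
      out <- find_compound_het(dplyr::bind_rows(v1, v2), GOOD_SEG)
      want <- oracle_phase(as.list(v1), as.list(v2))
      if (want == "CIS") {
        expect_equal(nrow(out), 0)
      } else {
        expect_equal(out$phase, want)
      }
      n_checked <- n_checked + 1
    }
    expect_equal(n_checked, 300)
  })
})

test_that("rare homozygous finder demands rarity, good region, and consistent parents", {
  ok <- tw_row(f = c(0L, 1L), m = c(0L, 1L), cc = c(1L, 1L), maf = 0.001)
  expect_equal(nrow(find_rare_homozygous(ok, GOOD_SEG)), 1)
  common <- dplyr::mutate(ok, maf_kg_global = 0.2)
  expect_equal(nrow(find_rare_homozygous(common, GOOD_SEG)), 0)
  # a hom-alt child with a non-carrier parent is an inheritance abnormality,
  # not a rare-homozygous candidate
  mia <- tw_row(f = c(0L, 0L), m = c(0L, 1L), cc = c(1L, 1L), maf = 0.001)
  expect_equal(nrow(find_rare_homozygous(mia, GOOD_SEG)), 0)
  expect_equal(nrow(find_rare_homozygous(ok, BAD_SEG)), 0)
})

test_that("hemizygosity needs a supporting deletion over a single-carrier-parent hom-alt child", {
  hemi <- tw_row(pos = 5000L, f = c(0L, 1L), m = c(0L, 0L), cc = c(1L, 1L))
  dels <- tibble::tibble(chrom = "1", start = 4900L, end = 5100L)
  out <- find_hemizygous(hemi, dels, GOOD_SEG)
  expect_equal(nrow(out), 1)
  expect_equal(out$deletion_start, 4900L)
  # no overlapping deletion: stays in the MIA channel
  far <- tibble::tibble(chrom = "1", start = 9000L, end = 9100L)
  expect_equal(nrow(find_hemizygous(hemi, far, GOOD_SEG)), 0)
  # het child is not hemizygous
  het <- tw_row(pos = 5000L, f = c(0L, 1L), m = c(0L, 0L), cc = c(0L, 1L))
  expect_equal(nrow(find_hemizygous(het, dels, GOOD_SEG)), 0)
  # both parents carrying the allele is ordinary inheritance
  both <- tw_row(pos = 5000L, f = c(0L, 1L), m = c(0L, 1L), cc = c(1L, 1L))
  expect_equal(nrow(find_hemizygous(both, dels, GOOD_SEG)), 0)
})

test_that("dominant-reduced-penetrance mode screens rare carried variants in listed genes", {
  v <- tw_row(f = c(0L, 1L), m = c(0L, 0L), cc = c(0L, 1L), gene = "DGENE",
              maf = 0.001)
  expect_equal(nrow(find_ad_reduced_penetrance(v, "DGENE")), 1)
  expect_equal(nrow(find_ad_reduced_penetrance(v, "OTHER")), 0)
  common <- dplyr::mutate(v, maf_kg_global = 0.2)
  expect_equal(nrow(find_ad_reduced_penetrance(common, "DGENE")), 0)
  # inherited from an unaffected carrier parent is allowed by design
  inherited <- tw_row(f = c(0L, 1L), m = c(0L, 0L), cc = c(0L, 1L),
                      gene = "DGENE", maf = NA_real_)
  expect_equal(nrow(find_ad_reduced_penetrance(inherited, "DGENE")), 1)
})

test_that("planted events are fully recovered and artifact regions contribute nothing", {
  sim <- simulate_trio(trio_sim_spec(seed = 23))
  dec <- viterbi_decode(encode_trio_observations(sim$calls, "FATHER", "MOTHER", "CHILD"))
  tw <- annotate_trio_sim(trio_wide(sim$calls, "FATHER", "MOTHER", "CHILD"), sim)
  cands <- trio_candidates(tw, dec, deletions = sim$deletions,
                           disease_genes = sim$disease_genes)
  man <- sim$manifest
  planted <- function(type) man$key[man$type == type & !man$artifact]
  expect_true(all(planted("de_novo") %in% cands$de_novo$key))
  expect_true(all(planted("rare_homozygous") %in% cands$rare_homozygous$key))
  expect_true(all(planted("hemizygous") %in% cands$hemizygous$key))
  expect_true(all(planted("ad_reduced_penetrance") %in%
                    cands$ad_reduced_penetrance$key))
  chm <- man[man$type == "compound_het", ]
  found_pairs <- paste(pmin(cands$compound_het$key1, cands$compound_het$key2),
                       pmax(cands$compound_het$key1, cands$compound_het$key2))
  want_pairs <- paste(pmin(chm$key, chm$partner_key),
                      pmax(chm$key, chm$partner_key))
  expect_true(all(want_pairs %in% found_pairs))
  ph <- cands$compound_het$phase[match(want_pairs, found_pairs)]
  expect_true(all(ph == chm$phase))
  # nothing reported from artifact (MIA-rich / compression) regions
  artifact_keys <- man$key[man$artifact]
  # interior of artifact tracts (boundary sites are only estimable to within
  # about one marker spacing)
  bad_region_keys <- sim$sites$key[sim$sites$true_state != "GOOD" & sim$sites$interior]
  mode_keys <- c(cands$de_novo$key, cands$rare_homozygous$key,
                 cands$hemizygous$key, cands$compound_het$key1,
                 cands$compound_het$key2)
  expect_equal(sum(artifact_keys %in% mode_keys), 0)
  expect_equal(sum(bad_region_keys %in% mode_keys), 0)
  # candidate lists are deduplicated
  expect_equal(anyDuplicated(cands$de_novo$key), 0)
  expect_equal(anyDuplicated(found_pairs), 0)
})
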