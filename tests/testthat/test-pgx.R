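# A small hand-built gene: 3 defining positions, alleles
#   *1 = ref/ref/ref, *2 = alt at p1, *3 = alt at p1+p2, *4 = alt at p3
STAR_DEFS <- tibble::tibble(
  gene = "CYPX",
  allele = c("*2", "*3", "*3", "*4"),
  chrom = "10",
  pos = c(100L, 100L, 200L, 300L),
  ref = c("A", "A", "C", "G"),
  alt = c("T", "T", "G", "A")
)

star_gt <- function(a_by_pos, status = c(p100 = "CALLED", p200 = "CALLED",
                                         p300 = "CALLED")) {
  tibble::tibble(
    chrom = "10", pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("T", "G", "A"),
    a1 = vapply(a_by_pos, `[`, integer(1), 1),
    a2 = vapply(a_by_pos, `[`, integer(1), 2),
    status = unname(status), sample = "S1", id = ".", qual = 99,
    filter = "PASS", phased = FALSE, dp = 50, gq = 99,
    key = paste("10", c(100L, 200L, 300L), c("A", "C", "G"), c("T", "G", "A"),
                sep = ":")
  )
}

test_that("skeletons pin homozygous calls and leave low-confidence positions unknown", {
  M <- varmend:::star_allele_matrix(STAR_DEFS, "CYPX")
  # all hom-ref
  sk <- build_skeleton(star_gt(list(c(0L, 0L), c(0L, 0L), c(0L, 0L))), M)
  expect_equal(unname(sk$hapA), c("A", "C", "G"))
  expect_equal(sk$hapA, sk$hapB)
  expect_equal(length(sk$het_positions), 0)
  # one hom-alt position pins both haplotypes
  sk <- build_skeleton(star_gt(list(c(1L, 1L), c(0L, 0L), c(0L, 0L))), M)
  expect_equal(unname(sk$hapA[1]), "T")
  expect_equal(unname(sk$hapB[1]), "T")
  # a low-confidence call is unknown on both haplotypes
  sk <- build_skeleton(star_gt(list(c(1L, 1L), c(0L, 0L), c(0L, 0L)),
                               status = c("CALLED", "LOW_CONFIDENCE", "CALLED")), M)
  expect_true(is.na(sk$hapA[2]) && is.na(sk$hapB[2]))
  # an uncovered position (no record) is unknown
  gt <- star_gt(list(c(0L, 0L), c(0L, 0L), c(0L, 0L)))[-3, ]
  sk <- build_skeleton(gt, M)
  expect_true(is.na(sk$hapA[3]))
})

test_that("diplotype enumeration yields max(1, 2^(h-1)) complementary pairs and honors the cap", {
  M <- varmend:::star_allele_matrix(STAR_DEFS, "CYPX")
  sk0 <- build_skeleton(star_gt(list(c(0L, 0L), c(0L, 0L), c(0L, 0L))), M)
  expect_equal(length(enumerate_diplotypes(sk0)), 1)
  sk1 <- build_skeleton(star_gt(list(c(0L, 1L), c(0L, 0L), c(0L, 0L))), M)
  expect_equal(length(enumerate_diplotypes(sk1)), 1)
  sk3 <- build_skeleton(star_gt(list(c(0L, 1L), c(0L, 1L), c(0L, 1L))), M)
  pairs <- enumerate_diplotypes(sk3)
  expect_equal(length(pairs), 4)  # 2^(3-1)
  # complementarity: at every called position the pair recombines to the genotype
  for (pr in pairs) {
    expect_setequal(c(pr$hapA["100"], pr$hapB["100"]), c("A", "T"))
    expect_setequal(c(pr$hapA["200"], pr$hapB["200"]), c("C", "G"))
    expect_setequal(c(pr$hapA["300"], pr$hapB["300"]), c("G", "A"))
  }
  # pairs are distinct as unordered objects
  sig <- vapply(pairs, function(pr) {
    paste(sort(c(paste(pr$hapA, collapse = ""), paste(pr$hapB, collapse = ""))),
          collapse = "|")
  }, character(1))
  expect_equal(anyDuplicated(sig), 0)
  # cap: refuse combinatorial blowups
  expect_error(enumerate_diplotypes(sk3, het_cap = 2), "cap")
})

test_that("perfect-match search resolves, reports ambiguity sets, or declines", {
  calls <- star_gt(list(c(0L, 1L), c(0L, 0L), c(0L, 0L)))  # *1/*2 uniquely
  out <- call_star_alleles(calls, STAR_DEFS, "S1")
  expect_equal(out$status, "RESOLVED")
  expect_equal(out$candidates[[1]], "*1/*2")
  # masking position 200 (the only position separating *2 from *3):
  # candidates must include both interpretations
  masked <- star_gt(list(c(0L, 1L), c(0L, 0L), c(0L, 0L)),
                    status = c("CALLED", "LOW_CONFIDENCE", "CALLED"))
  out <- call_star_alleles(masked, STAR_DEFS, "S1")
  expect_equal(out$status, "AMBIGUOUS")
  expect_true(all(c("*1/*2", "*1/*3") %in% out$candidates[[1]]))
  expect_equal(out$unknown_positions[[1]], "200")
  # a haplotype matching no definition yields UNASSIGNED with raw pairs
  # (alt at 200 without alt at 100 exists in no allele)
  odd <- star_gt(list(c(0L, 0L), c(1L, 1L), c(0L, 0L)))
  out <- call_star_alleles(odd, STAR_DEFS, "S1")
  expect_equal(out$status, "UNASSIGNED")
  expect_equal(out$n_candidates, 0)
  expect_gte(out$n_raw_pairs, 1)
  # unknown gene errors
  expect_error(call_star_alleles(calls, STAR_DEFS, "S1", genes = "NOPE"), "NOPE")
})

test_that("masked compatibility sets equal the exhaustive oracle and ambiguity is monotone", {
  withr::with_seed(31, {
    for (trial in 1:25) {
      fx <- make_star_fixture(seed = trial, n_alleles = 5, n_positions = 4)
      M <- varmend:::star_allele_matrix(fx$definitions, fx$gene)
      base <- call_star_alleles(fx$genotypes, fx$definitions, "S1")
      prev_set <- base$candidates[[1]]
      # mask positions one at a time; candidate set never shrinks
      for (k in 1:4) {
        fx_m <- make_star_fixture(seed = trial, n_alleles = 5, n_positions = 4,
                                  mask = seq_len(k))
        out <- call_star_alleles(fx_m$genotypes, fx_m$definitions, "S1")
        expect_true(all(prev_set %in% out$candidates[[1]]))
        prev_set <- out$candidates[[1]]
        # per-haplotype compatibility matches the oracle on the skeleton
        gt <- fx_m$genotypes
        sk <- build_skeleton(gt, M)
        pairs <- enumerate_diplotypes(sk)
        for (pr in pairs[seq_len(min(2, length(pairs)))]) {
          expect_setequal(varmend:::compatible_alleles(pr$hapA, M),
                          oracle_compatible(pr$hapA, M))
        }
      }
    }
  })
})

test_that("the true diplotype is always among the reported candidates", {
  hits <- vapply(1:60, function(s) {
    fx <- make_star_fixture(seed = s, n_alleles = 6, n_positions = 5)
    out <- call_star_alleles(fx$genotypes, fx$definitions, "S1")
    paste(fx$truth, collapse = "/") %in% out$candidates[[1]]
  }, logical(1))
  expect_true(all(hits))
})

test_that("fully informative genotypes with pairwise-distinct alleles resolve uniquely", {
  # fully called, no masking, identifiable definitions: exactly 1 candidate
  n1 <- vapply(1:30, function(s) {
    fx <- make_star_fixture(seed = s + 1000, n_alleles = 4, n_positions = 6,
                            disjoint = TRUE)
    call_star_alleles(fx$genotypes, fx$definitions, "S1")$n_candidates
  }, integer(1))
  expect_true(all(n1 == 1))
})

test_that("single-variant drug-response annotation honors the evidence-level scale and genotype", {
  kb <- tibble::tibble(
    chrom = "10", pos = c(100L, 100L, 200L), ref = c("A", "A", "C"),
    alt = c("T", "T", "G"),
    drug = c("warfarin", "clopidogrel", "simvastatin"),
    level = c("1A", "3", "2B"),
    annotation = c("dose", "metabolizer", "myopathy")
  )
  calls <- star_gt(list(c(0L, 1L), c(0L, 0L), c(0L, 0L)))
  out <- annotate_pgx_variants(calls, kb, min_level = "2B")
  # level 1A row emitted; level 3 suppressed; hom-ref genotype at 200 never annotated
  expect_equal(out$drug, "warfarin")
  out2 <- annotate_pgx_variants(calls, kb, min_level = "4")
  expect_setequal(out2$drug, c("warfarin", "clopidogrel"))
  # carrier rule across all three genotypes
  for (gt in list(c(0L, 0L), c(0L, 1L), c(1L, 1L))) {
    cl <- star_gt(list(gt, c(0L, 0L), c(0L, 0L)))
    n <- nrow(annotate_pgx_variants(cl, kb[1, ], min_level = "2B"))
    expect_equal(n, if (any(gt == 1L)) 1L else 0L)
  }
  # unknown level strings are skipped with a warning
  bad <- dplyr::mutate(kb, level = c("1A", "XX", "2B"))
  expect_warning(annotate_pgx_variants(calls, bad), "unknown")
})
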