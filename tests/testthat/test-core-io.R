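test_that("variant normalization trims to parsimonious left-aligned form", {
  out <- normalize_variants(c(100L, 100L, 100L), c("CT", "ATT", "A"),
                            c("CA", "AT", "G"))
  expect_equal(out$pos, c(101L, 100L, 100L))
  expect_equal(out$ref, c("T", "AT", "A"))
  expect_equal(out$alt, c("A", "A", "G"))
  expect_error(normalize_variants(100, "A", "A"), "differ")
})

test_that("normalization is idempotent, left-monotone, and matches the oracle on random indels", {
  withr::with_seed(11, {
    bases <- c("A", "C", "G", "T")
    for (i in 1:50) {
      nr <- sample(1:6, 1)
      na <- sample(1:6, 1)
      ref <- paste(sample(bases, nr, replace = TRUE), collapse = "")
      alt <- paste(sample(bases, na, replace = TRUE), collapse = "")
      if (ref == alt) next
      pos <- sample(1000:2000, 1)
      got <- normalize_variants(pos, ref, alt)
      exp <- oracle_normalize(pos, ref, alt)
      expect_equal(got$pos, exp$pos)
      expect_equal(got$ref, exp$ref)
      expect_equal(got$alt, exp$alt)
      # idempotent
      again <- normalize_variants(got$pos, got$ref, got$alt)
      expect_equal(again, got)
      # never moves left of the input position... and never right of the
      # trimmed ref end
      expect_gte(got$pos, pos)
    }
  })
})

test_that("read_vcf yields ordered per-sample records with confidence statuses", {
  calls <- read_vcf(write_trio_vcf())
  expect_setequal(unique(calls$sample), c("F", "M", "C"))
  # coordinate order
  sites <- dplyr::distinct(calls, chrom, pos)
  expect_true(all(diff(sites$pos[sites$chrom == "1"]) >= 0))
  # ./. becomes NO_CALL
  r300 <- calls[calls$pos == 301 & calls$sample == "C", ]  # CT>CA normalizes to 301
  expect_equal(r300$status, "NO_CALL")
  # depth 5 < 10 and GQ 10 < 20 are LOW_CONFIDENCE
  r400 <- calls[calls$pos == 400, ]
  expect_equal(r400$status[r400$sample == "F"], "LOW_CONFIDENCE")
  expect_equal(r400$status[r400$sample == "M"], "LOW_CONFIDENCE")
  expect_equal(r400$status[r400$sample == "C"], "CALLED")
  expect_true(r400$phased[r400$sample == "C"])
  # indel left-trimmed: ATT>AT at 150 -> AT>A at 150
  expect_true(any(calls$pos == 150 & calls$ref == "AT" & calls$alt == "A"))
  # requesting a missing sample is fatal and names it
  expect_error(read_vcf(write_trio_vcf(), samples = c("F", "M", "X")), "X")
})

test_that("multiallelic split remaps all six diploid genotypes and preserves allele multisets", {
  # hand enumeration for ref A, alt T,G with remap 0->0, k->1, other->2
  calls <- read_vcf(write_trio_vcf())
  r200 <- calls[calls$pos == 200, ]
  expect_equal(nrow(r200), 6)  # 2 biallelic records x 3 samples
  recT <- r200[r200$alt == "T", ]
  recG <- r200[r200$alt == "G", ]
  # F had 1/2: in record T -> (1,2); in record G -> (2,1)
  expect_equal(unname(unlist(recT[recT$sample == "F", c("a1", "a2")])), c(1L, 2L))
  expect_equal(unname(unlist(recG[recG$sample == "F", c("a1", "a2")])), c(2L, 1L))
  # M had 0/1 -> (0,1) and (0,2)
  expect_equal(unname(unlist(recT[recT$sample == "M", c("a1", "a2")])), c(0L, 1L))
  expect_equal(unname(unlist(recG[recG$sample == "M", c("a1", "a2")])), c(0L, 2L))
  # C had 0/2 -> (0,2) and (0,1)
  expect_equal(unname(unlist(recT[recT$sample == "C", c("a1", "a2")])), c(0L, 2L))
  expect_equal(unname(unlist(recG[recG$sample == "C", c("a1", "a2")])), c(0L, 1L))
  # multiset preservation: per sample, count of non-ref codes equals original
  for (s in c("F", "M", "C")) {
    n_nonref <- sum(unlist(r200[r200$sample == s, c("a1", "a2")]) != 0L)
    expect_equal(n_nonref / 2, c(F = 2, M = 1, C = 1)[[s]])
  }
})

test_that("VCF round-trip is lossless for the fields the pipeline touches", {
  sim <- simulate_trio(trio_sim_spec(seed = 5))
  p <- tempfile(fileext = ".vcf")
  write_vcf(sim$calls, p)
  back <- read_vcf(p)
  cols <- c("chrom", "pos", "ref", "alt", "key", "sample", "a1", "a2",
            "phased", "dp", "gq", "status", "filter")
  a <- dplyr::arrange(sim$calls[, cols], key, sample)
  b <- dplyr::arrange(back[, cols], key, sample)
  expect_equal(as.data.frame(a), as.data.frame(b))
  # writing unsorted input is fatal
  shuffled <- sim$calls[rev(seq_len(nrow(sim$calls))), ]
  expect_error(write_vcf(shuffled, tempfile(fileext = ".vcf")), "sorted")
})

test_that("region FILTER labels survive a write/read cycle and symbolic alts route to deletions", {
  sim <- simulate_trio(trio_sim_spec(seed = 5))
  seg <- tibble::tibble(chrom = "1", start = 0L, end = 10000000L,
                        state = "COMPRESSION", n_sites = 1L)
  lab <- apply_region_filters(sim$calls, seg)
  p <- tempfile(fileext = ".vcf")
  write_vcf(lab, p)
  hdr <- readLines(p, n = 20)
  expect_true(any(grepl("##FILTER=<ID=COMPRESSION", hdr)))
  back <- read_vcf(p)
  expect_true(all(grepl("COMPRESSION", back$filter[back$chrom == "1" & back$pos <= 1e7])))
  # <DEL> records become intervals
  del_vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t500\t.\tN\t<DEL>\t50\tPASS\tEND=900\tGT\t0/1",
    "1\t600\t.\tA\tT\t50\tPASS\t.\tGT\t0/1"
  ), del_vcf)
  dels <- read_deletion_intervals(del_vcf)
  expect_equal(nrow(dels), 1)
  expect_equal(dels$start, 500L)
  expect_equal(dels$end, 900L)
  expect_no_warning(calls <- read_vcf(del_vcf)) # <DEL> dropped silently
  expect_equal(unique(calls$pos), 600L)
})

test_that("BED and gene-list I/O round-trip with 0-based half-open semantics", {
  iv <- tibble::tibble(chrom = c("1", "2"), start = c(0L, 100L),
                       end = c(50L, 200L), label = c("a", "b"))
  p <- tempfile(fileext = ".bed")
  write_bed(iv, p)
  back <- read_bed(p)
  expect_equal(as.data.frame(back), as.data.frame(iv))
  gl <- tempfile()
  writeLines(c("GENE1", "", "# comment", "GENE2 "), gl)
  expect_equal(read_gene_list(gl), c("GENE1", "GENE2"))
})

test_that("clinical site report accounts for every queried locus", {
  calls <- read_vcf(write_trio_vcf())
  iv <- tibble::tibble(chrom = "1", start = 99L, end = 101L, label = "locus1")
  rep <- clinical_site_report(calls, iv)
  # pos 100 has records; pos 101 does not
  expect_equal(nrow(rep), 2 * 3)
  expect_equal(rep$status[rep$pos == 100 & rep$sample == "F"], "VARIANT_CALLED")
  expect_equal(rep$status[rep$pos == 100 & rep$sample == "M"], "HOM_REF_CALLED")
  expect_true(all(rep$status[rep$pos == 101] == "NO_CALL"))
  # depth sweep around the threshold (default 10)
  for (d in c(0, 5, 9, 10, 15, 20)) {
    one <- tibble::tibble(
      chrom = "1", pos = 100L, id = ".", ref = "A", alt = "T", qual = 50,
      filter = "PASS", key = "1:100:A:T", sample = "S", a1 = 0L, a2 = 0L,
      phased = FALSE, dp = d, gq = 99, status = if (d < 10) "LOW_CONFIDENCE" else "CALLED"
    )
    r <- clinical_site_report(one, tibble::tibble(chrom = "1", start = 99L,
                                                  end = 100L, label = "x"))
    expect_equal(r$status, if (d < 10) "LOW_COVERAGE" else "HOM_REF_CALLED")
  }
  # empty intervals give an empty table
  expect_equal(nrow(clinical_site_report(calls, iv[0, ])), 0)
})
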