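# In-code fixtures shared across tests.

# Minimal trio VCF text with assorted corner cases.
trio_vcf_lines <- function() {
  c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##contig=<ID=2>",
    "##FILTER=<ID=q10,Description=\"low qual\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "F", "M", "C"), collapse = "\t"),
    "1\t100\trs1\tA\tT\t50\tPASS\t.\tGT:DP:GQ\t0/1:40:99\t0/0:35:90\t0/1:42:95",
    "1\t200\t.\tA\tT,G\t60\tPASS\t.\tGT:DP:GQ\t1/2:30:80\t0/1:33:85\t0/2:31:88",
    "1\t300\t.\tCT\tCA\t40\tq10\t.\tGT:DP:GQ\t0/0:20:60\t0/1:22:70\t./.:.:.",
    "1\t400\t.\tG\tC\t90\tPASS\t.\tGT:DP:GQ\t0/0:5:99\t0/0:30:10\t1|1:50:99",
    "2\t150\t.\tATT\tAT\t70\tPASS\t.\tGT:DP:GQ\t0/1:45:99\t0/0:44:99\t0/1:46:99"
  )
}

write_trio_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(trio_vcf_lines(), path)
  path
}

# Construct a single-row trio-wide tibble directly.
tw_row <- function(chrom = "1", pos = 1000L, ref = "A", alt = "T",
                   f = c(0L, 0L), m = c(0L, 0L), cc = c(0L, 1L),
                   f_status = "CALLED", m_status = "CALLED",
                   c_status = "CALLED", gene = NA_character_,
                   maf = NA_real_) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), id = ".", ref = ref, alt = alt,
    qual = 100, filter = "PASS",
    key = paste(chrom, pos, ref, alt, sep = ":"),
    f_a1 = f[1], f_a2 = f[2], m_a1 = m[1], m_a2 = m[2],
    c_a1 = cc[1], c_a2 = cc[2],
    f_status = f_status, m_status = m_status, c_status = c_status,
    gene = gene, maf_kg_global = maf
  )
}

all_good_segments <- function(chroms = "1") {
  tibble::tibble(chrom = chroms, start = 0L, end = .Machine$integer.max,
                 state = "GOOD", n_sites = 0L)
}

random_hmm_params <- function() {
  em <- matrix(stats::runif(9, 0.05, 1), 3, 3)
  em <- em / rowSums(em)
  colnames(em) <- varmend::HMM_SYMBOLS
  rownames(em) <- varmend::HMM_STATES
  hmm_params(
    emissions = em,
    tract_lengths = stats::runif(3, 1e4, 1e7),
    stationary = stats::runif(3, 0.05, 1)
  )
}
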