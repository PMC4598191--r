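# VCF input/output. Parsing is delegated to vcfR; records are exposed as a
# long "calls" tibble (one row per biallelic variant x sample) so every
# downstream operation is an ordinary dplyr verb.

CALL_STATUS <- c("CALLED", "NO_CALL", "LOW_CONFIDENCE")

#' Read a VCF into a long calls tibble
#'
#' Returns one row per (biallelic variant, sample). Multiallelic records are
#' split into one record per alternate allele with allele indices remapped:
#' reference stays `0`, the record's own alternate becomes `1`, and any other
#' alternate allele of the original record is kept as the marker code `2`
#' ("other-alt"), so the multiset of per-sample alleles is preserved across
#' the split. Indel representations are left-trimmed to parsimonious form.
#'
#' Genotype confidence: a call with any missing allele has status `NO_CALL`;
#' a called genotype with depth below `min_depth` or genotype quality below
#' `min_gq` is `LOW_CONFIDENCE` (never treated as confidently called by
#' phasing or trio logic); everything else is `CALLED`.
#'
#' Symbolic alternate alleles are dropped with a warning; `<DEL>` records are
#' recoverable as intervals via [read_deletion_intervals()].
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples sample IDs to keep (default: all in the header). A
#'   requested sample missing from the header is a fatal error.
#' @param min_depth,min_gq low-confidence thresholds (defaults 10 and 20).
#' @param chrom_strip chromosome prefix stripped on input (default `"chr"`).
#' @return tibble with columns `chrom, pos, id, ref, alt, qual, filter, key,
#'   sample, a1, a2, phased, dp, gq, status`.
#' @export
read_vcf <- function(path, samples = NULL, min_depth = 10, min_gq = 20,
                     chrom_strip = "chr") {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  hdr_samples <- colnames(v@gt)[-1]
  samples <- samples %||% hdr_samples
  missing <- setdiff(samples, hdr_samples)
  if (length(missing) > 0) {
    abort(paste0("sample(s) not in VCF header: ", paste(missing, collapse = ", ")))
  }
  if (nrow(v@fix) == 0) {
    return(empty_calls())
  }
  fix <- v@fix[, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER"), drop = FALSE]
  gt_mat <- extract_fmt(v, "GT")
  dp_mat <- suppressWarnings(extract_fmt(v, "DP", numeric = TRUE))
  gq_mat <- suppressWarnings(extract_fmt(v, "GQ", numeric = TRUE))

  sites <- tibble(
    row = seq_len(nrow(fix)),
    chrom = harmonize_chrom(fix[, "CHROM"], chrom_strip),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"])
  )

  symbolic <- grepl("<", sites$alt, fixed = TRUE)
  if (any(symbolic)) {
    non_del <- setdiff(unique(unlist(strsplit(sites$alt[symbolic], ",", fixed = TRUE))), "<DEL>")
    non_del <- grep("^<", non_del, value = TRUE)
    if (length(non_del) > 0) {
      warn(paste0("dropping records with unsupported symbolic alts: ",
                  paste(non_del, collapse = ", ")))
    }
    sites <- sites[!symbolic, , drop = FALSE]
  }
  if (nrow(sites) == 0) return(empty_calls())

  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    alts <- strsplit(s$alt, ",", fixed = TRUE)[[1]]
    recs <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      gt_raw <- gt_mat[s$row, samples]
      parsed <- parse_gt(gt_raw, k = k)
      dp <- as.numeric(dp_mat[s$row, samples])
      gq <- as.numeric(gq_mat[s$row, samples])
      status <- call_status(parsed$a1, parsed$a2, dp, gq, min_depth, min_gq)
      recs[[k]] <- tibble(
        chrom = s$chrom, pos = s$pos, id = s$id, ref = s$ref, alt = alts[k],
        qual = s$qual, filter = s$filter,
        sample = samples,
        a1 = parsed$a1, a2 = parsed$a2, phased = parsed$phased,
        dp = dp, gq = gq, status = status
      )
    }
    out[[i]] <- bind_rows(recs)
  }
  res <- bind_rows(out)
  res <- add_variant_key(res)
  res <- arrange(res, .data$chrom, .data$pos, .data$ref, .data$alt,
                 match(.data$sample, samples))
  select(res, "chrom", "pos", "id", "ref", "alt", "qual", "filter", "key",
         "sample", "a1", "a2", "phased", "dp", "gq", "status")
}

empty_calls <- function() {
  tibble(
    chrom = character(), pos = integer(), id = character(), ref = character(),
    alt = character(), qual = numeric(), filter = character(), key = character(),
    sample = character(), a1 = integer(), a2 = integer(), phased = logical(),
    dp = numeric(), gq = numeric(), status = character()
  )
}

# vcfR::extract.gt with a fallback when a FORMAT field is absent entirely.
extract_fmt <- function(v, element, numeric = FALSE) {
  n <- nrow(v@fix)
  samples <- colnames(v@gt)[-1]
  m <- tryCatch(
    vcfR::extract.gt(v, element = element, as.numeric = numeric),
    error = function(e) NULL
  )
  if (is.null(m)) {
    m <- matrix(NA, nrow = n, ncol = length(samples))
  }
  m <- matrix(m, nrow = n, dimnames = list(NULL, samples))
  m
}

# Parse GT strings for alternate allele k of a (possibly multiallelic)
# record. Returns integer codes: 0 ref, 1 this alt, 2 other alt, NA missing.
parse_gt <- function(gt, k) {
  a1 <- a2 <- rep(NA_integer_, length(gt))
  phased <- rep(FALSE, length(gt))
  for (j in seq_along(gt)) {
    g <- gt[j]
    if (is.na(g) || g == ".") next
    phased[j] <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[/|]")[[1]]
    al <- suppressWarnings(as.integer(parts))
    remap <- function(x) {
      if (is.na(x)) NA_integer_
      else if (x == 0L) 0L
      else if (x == k) 1L
      else 2L
    }
    a1[j] <- remap(al[1])
    a2[j] <- if (length(al) >= 2) remap(al[2]) else NA_integer_
  }
  list(a1 = a1, a2 = a2, phased = phased)
}

call_status <- function(a1, a2, dp, gq, min_depth, min_gq) {
  status <- rep("CALLED", length(a1))
  low <- (!is.na(dp) & dp < min_depth) | (!is.na(gq) & gq < min_gq)
  status[low] <- "LOW_CONFIDENCE"
  status[is.na(a1) | is.na(a2)] <- "NO_CALL"
  status
}

#' Deletion intervals from symbolic `<DEL>` records
#'
#' Extracts `<DEL>` structural-variant records as 0-based half-open intervals
#' (`[POS, INFO/END)`), the support consumed by the hemizygosity finder.
#'
#' @inheritParams read_vcf
#' @return tibble `chrom, start, end`.
#' @export
read_deletion_intervals <- function(path, chrom_strip = "chr") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  fix <- v@fix
  is_del <- !is.na(fix[, "ALT"]) & fix[, "ALT"] == "<DEL>"
  if (!any(is_del)) return(tibble(chrom = character(), start = integer(), end = integer()))
  end <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  tibble(
    chrom = harmonize_chrom(fix[is_del, "CHROM"], chrom_strip),
    start = as.integer(fix[is_del, "POS"]),
    end = end[is_del]
  )
}

#' Write a calls tibble as a VCF file
#'
#' Emits standard VCF 4.2 with `GT:DP:GQ` per sample. FILTER header lines are
#' declared for the trio-HMM region labels (and any other label present), so
#' soft region filters written by [apply_region_filters()] round-trip. Input
#' must be coordinate-sorted. The "other-alt" allele marker (code 2, from
#' multiallelic splitting) is written as `.` since it is not representable in
#' a biallelic record.
#'
#' @param calls long calls tibble (see [read_vcf()]).
#' @param path output file.
#' @param filter_defs named character vector of FILTER id -> description to
#'   declare in the header (region labels are included by default).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path,
                      filter_defs = c(
                        COMPRESSION = "Trio HMM: reference-compression region",
                        MIA_RICH = "Trio HMM: Mendelian-inheritance-abnormality-rich region"
                      )) {
  samples <- unique(calls$sample)
  sites <- distinct(calls, .data$chrom, .data$pos, .data$id, .data$ref,
                    .data$alt, .data$qual, .data$filter)
  check_sorted(sites)
  used_filters <- setdiff(unique(unlist(strsplit(sites$filter, ";"))), c("PASS", "."))
  for (f in setdiff(used_filters, names(filter_defs))) {
    filter_defs[f] <- "Site-level filter"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    paste0("##FILTER=<ID=", names(filter_defs), ",Description=\"", filter_defs, "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  site_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  call_key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  body <- character(nrow(sites))
  fmt_allele <- function(a) ifelse(is.na(a) | a == 2L, ".", as.character(a))
  for (i in seq_len(nrow(sites))) {
    rows <- calls[call_key == site_key[i], ]
    rows <- rows[match(samples, rows$sample), ]
    gt <- paste0(fmt_allele(rows$a1), ifelse(rows$phased, "|", "/"), fmt_allele(rows$a2))
    dp <- ifelse(is.na(rows$dp), ".", format(rows$dp, trim = TRUE, scientific = FALSE))
    gq <- ifelse(is.na(rows$gq), ".", format(rows$gq, trim = TRUE, scientific = FALSE))
    body[i] <- paste(c(
      sites$chrom[i], sites$pos[i], sites$id[i], sites$ref[i], sites$alt[i],
      ifelse(is.na(sites$qual[i]), ".", format(sites$qual[i], trim = TRUE, scientific = FALSE)),
      sites$filter[i], ".", "GT:DP:GQ",
      paste(gt, dp, gq, sep = ":")
    ), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

check_sorted <- function(sites) {
  if (nrow(sites) < 2) return(invisible(TRUE))
  blocks <- rle(sites$chrom)$values
  if (anyDuplicated(blocks)) abort("records not coordinate-sorted: interleaved chromosomes")
  bad <- unlist(tapply(sites$pos, factor(sites$chrom, levels = blocks),
                       function(p) any(diff(p) < 0)))
  if (any(bad)) abort("records not coordinate-sorted within chromosome")
  invisible(TRUE)
}
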