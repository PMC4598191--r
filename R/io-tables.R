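# Interval, gene-list and annotation-table readers. All interval math inside
# the package is 0-based half-open; VCF positions are converted explicitly at
# the point of comparison (pos - 1).

#' Read a BED file of intervals
#'
#' BED is interpreted as 0-based half-open. Column 4, when present, becomes
#' the `label` column.
#' @param path BED file.
#' @param chrom_strip chromosome prefix stripped on input.
#' @return tibble `chrom, start, end, label`, sorted.
#' @export
read_bed <- function(path, chrom_strip = "chr") {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  if (ncol(df) < 3) abort("BED requires at least 3 columns")
  out <- tibble(
    chrom = harmonize_chrom(as.character(df[[1]]), chrom_strip),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    label = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  )
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#' @param intervals tibble with `chrom, start, end` and optionally a fourth
#'   column (e.g. `label` or `state`) written as BED column 4.
#' @param path output file.
#' @param name_col column to write as BED column 4 (default: `label` or
#'   `state` if present).
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  name_col <- name_col %||% intersect(c("label", "state"), names(intervals))[1]
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (length(name_col) == 1 && !is.na(name_col)) cols <- c(cols, list(intervals[[name_col]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#' @param path text file.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

# Annotation database ---------------------------------------------------------

#' Assemble an annotation database from tables
#'
#' Bundles the four lookup tables the tiering logic consumes. All variant
#' keys are normalized on construction; lookups are exact on the normalized
#' key, and a key absent from a table yields `NA` ("absent"), which is never
#' interpreted as zero.
#'
#' @param frequency tibble `chrom, pos, ref, alt, source, maf` (long; one row
#'   per population survey with data). Sources outside [FREQ_SOURCES] are
#'   rejected.
#' @param scores tibble `chrom, pos, ref, alt, gerp, phylop, sift, lrt,
#'   polyphen2, mutation_taster`.
#' @param reported tibble `chrom, pos, ref, alt, reported_effect`
#'   (reported-disease-mutation catalog membership).
#' @param genes tibble `gene, monogenic_flag` (monogenic-disease gene catalog).
#' @param local optional tibble `chrom, pos, ref, alt, af` of local-cohort
#'   site frequencies.
#' @return object of class `annotation_db`.
#' @export
annotation_db <- function(frequency, scores, reported, genes, local = NULL) {
  bad <- setdiff(unique(frequency$source), FREQ_SOURCES)
  if (length(bad) > 0) {
    abort(paste0("unknown frequency source(s): ", paste(bad, collapse = ", ")))
  }
  if (any(frequency$maf < 0 | frequency$maf > 1, na.rm = TRUE)) {
    abort("MAF values must lie in [0, 1]")
  }
  keyed <- function(df) {
    if (is.null(df)) return(df)
    df$key <- if (nrow(df) == 0) character(0)
              else variant_key(df$chrom, df$pos, df$ref, df$alt)
    df
  }
  structure(
    list(
      frequency = keyed(as_tibble(frequency)),
      scores = keyed(as_tibble(scores)),
      reported = keyed(as_tibble(reported)),
      genes = as_tibble(genes),
      local = if (!is.null(local)) keyed(as_tibble(local)) else NULL
    ),
    class = "annotation_db"
  )
}

#' Read an annotation database from TSV files
#'
#' @param frequency,scores,reported,genes,local paths to TSV tables with
#'   headers, in the layouts documented at [annotation_db()]. `local` may be
#'   `NULL`.
#' @return an `annotation_db`.
#' @export
read_annotation_db <- function(frequency, scores, reported, genes, local = NULL) {
  rd <- function(p) {
    df <- readr::read_tsv(p, show_col_types = FALSE)
    if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
    df
  }
  annotation_db(
    frequency = rd(frequency),
    scores = rd(scores),
    reported = rd(reported),
    genes = rd(genes),
    local = if (!is.null(local)) rd(local) else NULL
  )
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db>\n")
  cat("  frequency rows:", nrow(x$frequency), "\n")
  cat("  score rows:    ", nrow(x$scores), "\n")
  cat("  reported rows: ", nrow(x$reported), "\n")
  cat("  gene catalog:  ", nrow(x$genes), "genes,",
      sum(x$genes$monogenic_flag), "monogenic\n")
  cat("  local cohort:  ", if (is.null(x$local)) "none" else paste(nrow(x$local), "rows"), "\n")
  invisible(x)
}

# Interval utilities -----------------------------------------------------------

# For 1-based positions `pos` on `chrom`, return the row index of the interval
# (0-based half-open) containing each, or NA. Intervals need not be disjoint;
# the first match in sorted order wins.
interval_lookup <- function(chrom, pos, intervals) {
  idx <- rep(NA_integer_, length(pos))
  if (is.null(intervals) || nrow(intervals) == 0) return(idx)
  p0 <- pos - 1L
  for (ch in unique(chrom)) {
    iv <- which(intervals$chrom == ch)
    if (length(iv) == 0) next
    sel <- which(chrom == ch)
    for (i in sel) {
      hit <- iv[intervals$start[iv] <= p0[i] & p0[i] < intervals$end[iv]]
      if (length(hit) > 0) idx[i] <- hit[1]
    }
  }
  idx
}

#' Assign gene labels by interval overlap
#'
#' Adds a `gene` column by locating each variant position within a table of
#' gene spans (0-based half-open).
#' @param df tibble with `chrom`, `pos`.
#' @param gene_intervals tibble `gene, chrom, start, end`.
#' @export
assign_genes <- function(df, gene_intervals) {
  idx <- interval_lookup(df$chrom, df$pos, gene_intervals)
  df$gene <- gene_intervals$gene[idx]
  df
}

# Clinical-site reporting ------------------------------------------------------

#' Per-position call/coverage report over clinical loci
#'
#' Accounts for every queried position of every interval, per sample, so a
#' disease-associated allele can be asserted absent (confident reference
#' call) rather than merely not reported. Status is `LOW_COVERAGE` when depth
#' is known and below `min_depth`; `NO_CALL` when no record covers the
#' position or the genotype is missing/low-confidence; otherwise
#' `VARIANT_CALLED` or `HOM_REF_CALLED`.
#'
#' @param calls long calls tibble.
#' @param intervals tibble `chrom, start, end, label` (0-based half-open);
#'   intended for short clinical loci (the report is per-position).
#' @param min_depth coverage threshold (default 10).
#' @return tibble `chrom, pos, label, sample, status, depth`.
#' @export
clinical_site_report <- function(calls, intervals, min_depth = 10) {
  samples <- unique(calls$sample)
  if (is.null(intervals) || nrow(intervals) == 0 || length(samples) == 0) {
    return(tibble(chrom = character(), pos = integer(), label = character(),
                  sample = character(), status = character(), depth = numeric()))
  }
  grid <- purrr::pmap(intervals, function(chrom, start, end, label = NA_character_, ...) {
    tibble(chrom = chrom, pos = seq.int(start + 1L, end), label = label)
  })
  grid <- tidyr::expand_grid(bind_rows(grid), sample = samples)
  hit <- left_join(grid, calls,
                   by = c("chrom", "pos", "sample"),
                   relationship = "many-to-many")
  hit <- hit %>%
    mutate(
      status_site = case_when(
        is.na(.data$status) ~ "NO_CALL",
        !is.na(.data$dp) & .data$dp < min_depth ~ "LOW_COVERAGE",
        .data$status != "CALLED" ~ "NO_CALL",
        .data$a1 > 0 | .data$a2 > 0 ~ "VARIANT_CALLED",
        TRUE ~ "HOM_REF_CALLED"
      )
    ) %>%
    group_by(.data$chrom, .data$pos, .data$label, .data$sample) %>%
    summarise(
      status = if (any(.data$status_site == "VARIANT_CALLED")) "VARIANT_CALLED"
               else .data$status_site[1],
      depth = suppressWarnings(max(.data$dp, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    mutate(depth = ifelse(is.infinite(.data$depth), NA_real_, .data$depth))
  arrange(hit, .data$chrom, .data$pos, .data$sample)
}
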