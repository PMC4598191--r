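# Variant key normalization: left-trimmed, parsimonious representation.

#' Normalize variant representations
#'
#' Reduces each (pos, ref, alt) to its parsimonious left-aligned form by
#' trimming the shared suffix and then the shared prefix, adjusting the
#' position for every leading base removed. Both alleles always retain at
#' least one base. The operation is idempotent and never moves a variant
#' rightwards.
#'
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of reference / alternate alleles
#'   (non-empty, `ref != alt` elementwise).
#' @return A tibble with columns `pos`, `ref`, `alt`.
#' @examples
#' normalize_variants(100, "CT", "CA")   # -> pos 101, T > A
#' normalize_variants(100, "ATT", "AT")  # -> pos 100, AT > A
#' @export
normalize_variants <- function(pos, ref, alt) {
  n <- length(pos)
  stopifnot(length(ref) == n, length(alt) == n)
  if (any(ref == alt)) {
    abort("ref and alt must differ: not a variant")
  }
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    abort("ref and alt must be non-empty allele strings")
  }
  out_pos <- as.integer(pos)
  out_ref <- ref
  out_alt <- alt
  for (i in seq_len(n)) {
    r <- out_ref[i]
    a <- out_alt[i]
    p <- out_pos[i]
    # shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # shared prefix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    out_ref[i] <- r
    out_alt[i] <- a
    out_pos[i] <- p
  }
  tibble(pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Normalized variant key
#'
#' `chrom:pos:ref:alt` after [normalize_variants()]; the exact-match key used
#' by every annotation, catalog, and star-allele lookup.
#'
#' @inheritParams normalize_variants
#' @param chrom chromosome labels.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  nv <- normalize_variants(pos, ref, alt)
  paste(chrom, nv$pos, nv$ref, nv$alt, sep = ":")
}

#' Harmonize chromosome name dialects
#'
#' Strips a leading prefix (default `"chr"`) so that `chr1` and `1` compare
#' equal across inputs.
#' @param chrom character vector.
#' @param strip prefix to remove; `NULL` disables harmonization.
#' @export
harmonize_chrom <- function(chrom, strip = "chr") {
  if (is.null(strip) || !nzchar(strip)) return(chrom)
  sub(paste0("^", strip), "", chrom)
}

# Add/refresh the normalized key column of a variant tibble.
add_variant_key <- function(df) {
  nv <- normalize_variants(df$pos, df$ref, df$alt)
  df$pos <- nv$pos
  df$ref <- nv$ref
  df$alt <- nv$alt
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df
}
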