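# Independent oracles. Each is coded from the definition, by a different
# route than the implementation it checks.

# Parsimonious left-trim by arithmetic on common suffix/prefix lengths
# (implementation trims with a character loop).
oracle_normalize <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# Exhaustive maximum-probability path over all 3^n state sequences.
oracle_viterbi <- function(pos, symbols, params) {
  n <- length(pos)
  sym_idx <- match(symbols, varmend::HMM_SYMBOLS)
  A <- lapply(seq_len(max(n - 1, 0)), function(t) {
    transition_matrix(pos[t + 1] - pos[t], params)
  })
  best <- NULL
  best_lp <- -Inf
  grid <- expand.grid(rep(list(1:3), n))[, n:1, drop = FALSE]  # lexicographic
  for (r in seq_len(nrow(grid))) {
    path <- as.integer(grid[r, ])
    lp <- log(params$stationary[path[1]]) + log(params$emissions[path[1], sym_idx[1]])
    if (n > 1) {
      for (t in 2:n) {
        lp <- lp + log(A[[t - 1]][path[t - 1], path[t]]) +
          log(params$emissions[path[t], sym_idx[t]])
      }
    }
    if (lp > best_lp) {
      best_lp <- lp
      best <- path
    }
  }
  list(path = varmend::HMM_STATES[best], loglik = best_lp)
}

# Decision-table tiering, coded independently: explicit predicate
# computation with loops, then nested if/else per track.
oracle_tier <- function(row, maf_threshold = 0.01, large = 50) {
  sources <- paste0("maf_", varmend::FREQ_SOURCES)
  worst <- -Inf
  for (s in sources) {
    v <- row[[s]]
    if (!is.null(v) && length(v) == 1 && !is.na(v) && v > worst) worst <- v
  }
  rare <- is.infinite(worst) || worst <= maf_threshold
  ilen <- abs(nchar(row$ref) - nchar(row$alt))
  lof <- row$effect %in% c("SPLICE_DINUCLEOTIDE", "NONSENSE", "NONSTOP",
                           "FRAMESHIFT_INDEL", "LARGE_CODING_INDEL") ||
    (row$effect == "NONFRAMESHIFT_INDEL" && ilen >= large)
  cons <- !is.na(row$gerp) && row$gerp > 2 && !is.na(row$phylop) && row$phylop > 0.95
  votes <- 0
  if (!is.na(row$sift) && row$sift == "Damaging") votes <- votes + 1
  if (!is.na(row$lrt) && row$lrt == "Deleterious") votes <- votes + 1
  if (!is.na(row$polyphen2) && row$polyphen2 %in% c("Probably damaging", "Possibly damaging")) votes <- votes + 1
  if (!is.na(row$mutation_taster) && row$mutation_taster %in% c("Disease causing automatic", "Disease causing")) votes <- votes + 1
  path <- votes >= 3
  t3class <- row$effect %in% c("MISSENSE", "NONFRAMESHIFT_INDEL")

  rep_tier <- if (!row$reported) NA_integer_
  else if (lof) 1L
  else if (rare) 2L
  else if (t3class) 3L
  else 4L

  nov_tier <- if (row$reported || !row$in_monogenic_gene || !rare) NA_integer_
  else if (lof) 1L
  else if ((row$effect == "MISSENSE" && cons) || row$effect == "NONFRAMESHIFT_INDEL") 2L
  else if (row$effect == "MISSENSE" && path) 3L
  else 4L

  list(reported = rep_tier, novel = nov_tier)
}

# Rarity by explicit loop over present sources.
oracle_is_rare <- function(row, threshold = 0.01) {
  vals <- c()
  for (s in paste0("maf_", varmend::FREQ_SOURCES)) {
    v <- row[[s]]
    if (!is.null(v) && !is.na(v)) vals <- c(vals, v)
  }
  if (length(vals) == 0) TRUE else max(vals) <= threshold
}

# Compound-het phase by enumeration of parental transmission assignments.
# For each variant, the set of parents able to donate the child's alternate
# allele in at least one full assignment; classification as in the finder.
oracle_phase <- function(v1, v2) {
  origins <- function(v) {
    f <- c(v$f_a1, v$f_a2)
    m <- c(v$m_a1, v$m_a2)
    kid <- c(v$c_a1, v$c_a2)
    out <- character(0)
    for (fi in 1:2) for (mi in 1:2) {
      if (identical(sort(c(f[fi], m[mi])), sort(kid))) {
        if (f[fi] == 1L) out <- c(out, "father")
        if (m[mi] == 1L) out <- c(out, "mother")
      }
    }
    unique(out)
  }
  o1 <- origins(v1)
  o2 <- origins(v2)
  only <- function(o, p) length(o) == 1 && o == p
  if ((only(o1, "father") && only(o2, "mother")) ||
      (only(o1, "mother") && only(o2, "father"))) return("TRANS_CONFIRMED")
  if ((only(o1, "father") && only(o2, "father")) ||
      (only(o1, "mother") && only(o2, "mother"))) return("CIS")
  "PHASE_UNKNOWN"
}

# Star alleles compatible with a partially known haplotype, recomputed from
# the definition matrix.
oracle_compatible <- function(hap, M) {
  out <- character(0)
  for (al in rownames(M)) {
    ok <- TRUE
    for (p in colnames(M)) {
      if (!is.na(hap[p]) && hap[p] != M[al, p]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, al)
  }
  out
}
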