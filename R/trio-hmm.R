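# Three-state HMM over ordered trio genotype observations.
#
# Observations are per-site trio symbols: MIA (child genotype impossible
# under one-allele-from-each-parent transmission), ALLHET (all three
# heterozygous, the signature of reference-compression regions), else
# CONSISTENT; precedence MIA > ALLHET > CONSISTENT. Hidden states are GOOD,
# COMPRESSION, MIA_RICH. Transition probabilities are scaled by the physical
# distance between adjacent markers — the stay probability of state s over a
# gap of d bp is exp(-d / L_s) with L_s the expected tract length — so the
# model behaves sensibly on both dense WGS and sparse capture data.

#' Trio HMM parameters
#'
#' @param emissions 3x3 row-stochastic matrix, rows = states
#'   (GOOD, COMPRESSION, MIA_RICH), columns = symbols
#'   (CONSISTENT, MIA, ALLHET). Defaults: good data emits MIA at roughly the
#'   sequencing-error scale (0.001) and ALLHET at the background
#'   heterozygosity coincidence rate (0.01); compression regions are dominated
#'   by universal heterozygosity; MIA-rich regions by inheritance errors.
#' @param tract_lengths expected tract length per state in bp
#'   (defaults: 10 Mb good data, 100 kb for both artifact states).
#' @param stationary stationary state weights (default 0.98/0.01/0.01); used
#'   both as the initial distribution and to apportion leave probability.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(emissions = NULL,
                       tract_lengths = c(GOOD = 1e7, COMPRESSION = 1e5, MIA_RICH = 1e5),
                       stationary = c(GOOD = 0.98, COMPRESSION = 0.01, MIA_RICH = 0.01)) {
  if (is.null(emissions)) {
    emissions <- rbind(
      GOOD        = c(0.989, 0.001, 0.010),
      COMPRESSION = c(0.400, 0.100, 0.500),
      MIA_RICH    = c(0.550, 0.400, 0.050)
    )
    colnames(emissions) <- HMM_SYMBOLS
  }
  emissions <- as.matrix(emissions)
  stopifnot(nrow(emissions) == 3, ncol(emissions) == 3)
  if (any(emissions <= 0 | emissions >= 1)) abort("emission probabilities must be in (0,1)")
  if (any(abs(rowSums(emissions) - 1) > 1e-9)) abort("emission rows must sum to 1")
  stationary <- stationary / sum(stationary)
  if (any(tract_lengths <= 0)) abort("tract lengths must be positive")
  structure(
    list(
      states = HMM_STATES, symbols = HMM_SYMBOLS,
      emissions = matrix(emissions, 3, 3,
                         dimnames = list(HMM_STATES, HMM_SYMBOLS)),
      tract_lengths = setNames(as.numeric(tract_lengths), HMM_STATES),
      stationary = setNames(as.numeric(stationary), HMM_STATES)
    ),
    class = "hmm_params"
  )
}

#' Distance-scaled transition matrix
#'
#' Stay probability of state s over a marker gap of `distance_bp` is
#' `exp(-distance_bp / L_s)`; leave probability is split between the other
#' two states proportionally to their stationary weights. Rows sum to one; a
#' zero gap gives the identity.
#'
#' @param distance_bp non-negative gap between adjacent markers.
#' @param params an [hmm_params()].
#' @return 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(distance_bp, params = hmm_params()) {
  if (distance_bp < 0) abort("distance must be non-negative")
  stay <- exp(-distance_bp / params$tract_lengths)
  pi <- params$stationary
  A <- matrix(0, 3, 3, dimnames = list(HMM_STATES, HMM_STATES))
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    A[i, i] <- stay[i]
    A[i, others] <- (1 - stay[i]) * pi[others] / sum(pi[others])
  }
  A
}

# Trio observation encoding ----------------------------------------------------

#' Pivot a long calls tibble into one row per variant with trio roles
#'
#' @param calls long calls tibble.
#' @param father,mother,child sample IDs; an ID missing from the calls is a
#'   fatal error.
#' @return tibble with per-role genotype columns (`f_a1 ... c_status`) plus
#'   the variant columns.
#' @export
trio_wide <- function(calls, father, mother, child) {
  roles <- c(f = father, m = mother, c = child)
  missing <- setdiff(roles, unique(calls$sample))
  if (length(missing) > 0) {
    abort(paste0("trio sample(s) absent from calls: ", paste(missing, collapse = ", ")))
  }
  sub <- calls %>%
    filter(.data$sample %in% roles) %>%
    mutate(role = names(roles)[match(.data$sample, roles)])
  tidyr::pivot_wider(
    sub,
    id_cols = c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "key"),
    names_from = "role",
    values_from = c("a1", "a2", "phased", "dp", "gq", "status"),
    names_glue = "{role}_{.value}"
  ) %>%
    arrange(.data$chrom, .data$pos)
}

# Mendelian consistency of one biallelic trio genotype: can the child receive
# one allele from each parent?
trio_consistent <- function(f1, f2, m1, m2, c1, c2) {
  from_f <- function(x) x == f1 | x == f2
  from_m <- function(x) x == m1 | x == m2
  (from_f(c1) & from_m(c2)) | (from_f(c2) & from_m(c1))
}

#' Encode trio genotypes as HMM observation symbols
#'
#' Only sites where all three samples are confidently CALLED contribute
#' observations; by default only SNVs (indel inheritance-error rates are
#' caller-dependent). Symbols follow the precedence MIA > ALLHET >
#' CONSISTENT. The Y chromosome is always excluded; X is included only for
#' female children (hemizygous male X calls follow no diploid transmission
#' model), and an unknown child sex is handled like male.
#'
#' @param calls long calls tibble.
#' @param father,mother,child sample IDs.
#' @param include_indels include indel sites as observations (default FALSE).
#' @param child_sex `"unknown"`, `"female"`, or `"male"`.
#' @return tibble `chrom, pos, key, symbol`, position-sorted.
#' @export
encode_trio_observations <- function(calls, father, mother, child,
                                     include_indels = FALSE,
                                     child_sex = c("unknown", "female", "male")) {
  child_sex <- match.arg(child_sex)
  tw <- trio_wide(calls, father, mother, child)
  tw <- filter(tw, !.data$chrom %in% c("Y", "chrY"))
  if (child_sex != "female") tw <- filter(tw, !.data$chrom %in% c("X", "chrX"))
  tw <- filter(tw,
               .data$f_status == "CALLED", .data$m_status == "CALLED",
               .data$c_status == "CALLED")
  if (!include_indels) {
    tw <- filter(tw, nchar(.data$ref) == 1L, nchar(.data$alt) == 1L)
  }
  # exclude sites carrying the other-alt marker (not biallelic in this record)
  tw <- filter(tw, dplyr::if_all(c("f_a1", "f_a2", "m_a1", "m_a2", "c_a1", "c_a2"),
                                 ~ .x %in% c(0L, 1L)))
  if (nrow(tw) == 0) {
    return(tibble(chrom = character(), pos = integer(), key = character(),
                  symbol = character()))
  }
  consistent <- trio_consistent(tw$f_a1, tw$f_a2, tw$m_a1, tw$m_a2, tw$c_a1, tw$c_a2)
  allhet <- tw$f_a1 != tw$f_a2 & tw$m_a1 != tw$m_a2 & tw$c_a1 != tw$c_a2
  symbol <- ifelse(!consistent, "MIA", ifelse(allhet, "ALLHET", "CONSISTENT"))
  tibble(chrom = tw$chrom, pos = tw$pos, key = tw$key, symbol = symbol) %>%
    arrange(.data$chrom, .data$pos)
}

# Viterbi ----------------------------------------------------------------------

viterbi_chrom <- function(pos, symbols, params) {
  n <- length(pos)
  logE <- log(params$emissions)
  sym_idx <- match(symbols, HMM_SYMBOLS)
  delta <- matrix(-Inf, n, 3)
  psi <- matrix(0L, n, 3)
  delta[1, ] <- log(params$stationary) + logE[, sym_idx[1]]
  if (n > 1) {
    for (t in 2:n) {
      logA <- log(transition_matrix(pos[t] - pos[t - 1], params))
      for (j in 1:3) {
        cand <- delta[t - 1, ] + logA[, j]
        b <- which.max(cand)  # first maximum: ties resolve toward GOOD
        psi[t, j] <- b
        delta[t, j] <- cand[b] + logE[j, sym_idx[t]]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  list(path = HMM_STATES[path], loglik = max(delta[n, ]))
}

# Log-space forward-backward posteriors for one chromosome.
posterior_chrom <- function(pos, symbols, params) {
  n <- length(pos)
  logE <- log(params$emissions)
  sym_idx <- match(symbols, HMM_SYMBOLS)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  fwd <- matrix(-Inf, n, 3)
  bwd <- matrix(0, n, 3)
  fwd[1, ] <- log(params$stationary) + logE[, sym_idx[1]]
  if (n > 1) {
    for (t in 2:n) {
      logA <- log(transition_matrix(pos[t] - pos[t - 1], params))
      for (j in 1:3) fwd[t, j] <- lse(fwd[t - 1, ] + logA[, j]) + logE[j, sym_idx[t]]
    }
    for (t in (n - 1):1) {
      logA <- log(transition_matrix(pos[t + 1] - pos[t], params))
      for (i in 1:3) bwd[t, i] <- lse(logA[i, ] + logE[, sym_idx[t + 1]] + bwd[t + 1, ])
    }
  }
  g <- fwd + bwd
  g <- g - apply(g, 1, lse)
  exp(g)
}

#' Viterbi decoding of trio observations into inheritance segments
#'
#' Computes the maximum a posteriori joint state path per chromosome in log
#' space (ties broken toward GOOD, then toward the lower state index) and
#' collapses it into maximal segments. Segment boundaries fall at the
#' midpoints between adjacent observed sites; chromosome ends extend only to
#' the first/last observation. Segments are 0-based half-open.
#'
#' @param observations tibble `chrom, pos, symbol` (position-sorted per
#'   chromosome), from [encode_trio_observations()].
#' @param params an [hmm_params()].
#' @param posterior also run forward-backward and report each segment's mean
#'   posterior probability of its assigned state.
#' @return object of class `trio_decode`: list with `path` (per-site tibble
#'   adding `state`), `segments` (tibble `chrom, start, end, state, n_sites`,
#'   plus `mean_posterior` when requested), and `params`.
#' @export
viterbi_decode <- function(observations, params = hmm_params(), posterior = FALSE) {
  obs <- arrange(as_tibble(observations), .data$chrom, .data$pos)
  if (!all(obs$symbol %in% HMM_SYMBOLS)) abort("unknown observation symbol")
  path_list <- list()
  seg_list <- list()
  for (ch in unique(obs$chrom)) {
    o <- obs[obs$chrom == ch, ]
    n <- nrow(o)
    vt <- viterbi_chrom(o$pos, o$symbol, params)
    post <- if (posterior) posterior_chrom(o$pos, o$symbol, params) else NULL
    path_list[[ch]] <- mutate(o, state = vt$path)
    r <- rle(vt$path)
    ends_i <- cumsum(r$lengths)
    starts_i <- c(1L, head(ends_i, -1) + 1L)
    prev_pos <- o$pos[pmax(starts_i - 1L, 1L)]
    seg_start <- ifelse(starts_i == 1L, o$pos[1] - 1L,
                        (prev_pos + o$pos[starts_i]) %/% 2L)
    seg_end <- ifelse(ends_i == n, o$pos[n],
                      (o$pos[ends_i] + o$pos[pmin(ends_i + 1L, n)]) %/% 2L)
    seg <- tibble(chrom = ch, start = as.integer(seg_start),
                  end = as.integer(seg_end), state = r$values,
                  n_sites = r$lengths)
    if (posterior) {
      seg$mean_posterior <- vapply(seq_len(nrow(seg)), function(k) {
        idx <- starts_i[k]:ends_i[k]
        mean(post[cbind(idx, match(r$values[k], HMM_STATES))])
      }, numeric(1))
    }
    seg_list[[ch]] <- seg
  }
  structure(
    list(path = bind_rows(path_list), segments = bind_rows(seg_list),
         params = params),
    class = "trio_decode"
  )
}

#' @export
print.trio_decode <- function(x, ...) {
  cat("<trio_decode>", nrow(x$path), "observations,",
      nrow(x$segments), "segments\n")
  print(count(x$segments, .data$state, wt = .data$n_sites, name = "sites"))
  invisible(x)
}

# Region filtering ---------------------------------------------------------------

#' Soft-label records inside artifact regions
#'
#' Appends `COMPRESSION` or `MIA_RICH` to the FILTER field of every record
#' whose position falls inside such a segment. Records in GOOD segments, or
#' on contigs with no segments, are untouched; no record is ever dropped.
#'
#' @param calls calls tibble (long or any tibble with `chrom, pos, filter`).
#' @param segments segment tibble from [viterbi_decode()] (or its `segments`
#'   element).
#' @return `calls` with updated `filter`.
#' @export
apply_region_filters <- function(calls, segments) {
  if (inherits(segments, "trio_decode")) segments <- segments$segments
  bad <- filter(segments, .data$state != "GOOD")
  if (nrow(bad) == 0) return(calls)
  idx <- interval_lookup(calls$chrom, calls$pos, bad)
  lab <- bad$state[idx]
  upd <- !is.na(lab)
  new_filter <- calls$filter
  blank <- upd & (is.na(new_filter) | new_filter %in% c(".", "PASS", ""))
  new_filter[blank] <- lab[blank]
  for (i in which(upd & !blank)) {
    existing <- strsplit(new_filter[i], ";", fixed = TRUE)[[1]]
    if (!lab[i] %in% existing) {
      new_filter[i] <- paste(new_filter[i], lab[i], sep = ";")
    }
  }
  calls$filter <- new_filter
  calls
}

# State of the segment containing each position; positions outside every
# segment (unobserved contigs) default to GOOD — filtering only ever removes
# regions positively identified as artifact.
region_state <- function(chrom, pos, segments) {
  if (inherits(segments, "trio_decode")) segments <- segments$segments
  if (is.null(segments) || nrow(segments) == 0) return(rep("GOOD", length(pos)))
  idx <- interval_lookup(chrom, pos, segments)
  out <- segments$state[idx]
  out[is.na(out)] <- "GOOD"
  out
}
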