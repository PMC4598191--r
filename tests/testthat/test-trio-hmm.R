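test_that("trio symbols follow the MIA > ALLHET > CONSISTENT precedence and call requirements", {
  mk <- function(f, m, cc, status = "CALLED") {
    dplyr::bind_rows(lapply(list(c("FA", f), c("MO", m), c("CH", cc)), function(x) {
      tibble::tibble(chrom = "1", pos = 100L, id = ".", ref = "A", alt = "T",
                     qual = 50, filter = "PASS", key = "1:100:A:T",
                     sample = x[1], a1 = as.integer(x[2]), a2 = as.integer(x[3]),
                     phased = FALSE, dp = 40, gq = 99, status = status)
    }))
  }
  enc <- function(calls) encode_trio_observations(calls, "FA", "MO", "CH")
  expect_equal(enc(mk(c(0, 0), c(0, 0), c(0, 1)))$symbol, "MIA")
  expect_equal(enc(mk(c(0, 1), c(0, 1), c(0, 1)))$symbol, "ALLHET")
  expect_equal(enc(mk(c(0, 1), c(0, 0), c(0, 1)))$symbol, "CONSISTENT")
  expect_equal(enc(mk(c(0, 1), c(0, 1), c(1, 1)))$symbol, "CONSISTENT")
  # a NO_CALL anywhere drops the site from the observations
  nc <- mk(c(0, 0), c(0, 0), c(0, 1))
  nc$status[nc$sample == "FA"] <- "NO_CALL"
  expect_equal(nrow(enc(nc)), 0)
  # low-confidence calls are never treated as called
  lc <- mk(c(0, 0), c(0, 0), c(0, 1), status = "LOW_CONFIDENCE")
  expect_equal(nrow(enc(lc)), 0)
  # Y sites never contribute; X only for female children
  xy <- mk(c(0, 1), c(0, 0), c(0, 1))
  xy$chrom <- "X"; xy$key <- "X:100:A:T"
  expect_equal(nrow(enc(xy)), 0)
  expect_equal(nrow(encode_trio_observations(xy, "FA", "MO", "CH",
                                             child_sex = "female")), 1)
})

test_that("ALLHET is consistent by transmission enumeration but flagged by precedence", {
  # all four transmissions from het x het parents cover 0/0, 0/1, 1/1: the
  # all-het trio is Mendelian-consistent, so its flag must come from the
  # precedence rule, not from inconsistency
  f <- c(0L, 1L); m <- c(0L, 1L)
  kids <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  transmissions <- expand.grid(fi = 1:2, mi = 1:2)
  reachable <- apply(transmissions, 1, function(t) {
    paste(sort(c(f[t["fi"]], m[t["mi"]])), collapse = "/")
  })
  expect_true("0/1" %in% reachable)
})

test_that("transition matrix has the stated closed form", {
  p <- hmm_params()
  # zero distance: identity
  expect_equal(transition_matrix(0, p), diag(3), ignore_attr = TRUE)
  # stay probability at d = L is exactly exp(-1)
  d <- p$tract_lengths["GOOD"]
  expect_equal(transition_matrix(d, p)["GOOD", "GOOD"], exp(-1),
               tolerance = 1e-14)
  # rows sum to one and stay probabilities strictly decrease with distance
  prev <- c(1, 1, 1)
  for (d in c(1, 10, 1e3, 1e5, 1e7, 1e9)) {
    A <- transition_matrix(d, p)
    expect_equal(unname(rowSums(A)), c(1, 1, 1), tolerance = 1e-12)
    stay <- diag(A)
    expect_true(all(stay < prev))
    prev <- stay
  }
  # infinite distance: each row converges to the stationary weights
  # renormalized over the other two states
  A <- transition_matrix(1e12, p)
  pi <- p$stationary
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    expect_equal(unname(A[i, others]), unname(pi[others] / sum(pi[others])),
                 tolerance = 1e-9)
  }
  expect_error(transition_matrix(-1, p), "non-negative")
})

test_that("Viterbi equals brute-force path enumeration on random short instances", {
  withr::with_seed(101, {
    for (trial in 1:50) {
      n <- sample(2:8, 1)
      pos <- sort(sample(1:100000, n))
      symbols <- sample(HMM_SYMBOLS, n, replace = TRUE)
      params <- random_hmm_params()
      obs <- tibble::tibble(chrom = "1", pos = pos, symbol = symbols)
      got <- viterbi_decode(obs, params)
      want <- oracle_viterbi(pos, symbols, params)
      expect_equal(got$path$state, want$path)
    }
  })
})

test_that("homogeneous and planted-run inputs decode as expected", {
  # all-consistent: all GOOD under default parameters
  obs <- tibble::tibble(chrom = "1", pos = seq(1000, 100000, by = 1000),
                        symbol = "CONSISTENT")
  dec <- viterbi_decode(obs)
  expect_true(all(dec$path$state == "GOOD"))
  expect_equal(nrow(dec$segments), 1)
  # a run of 20 MIAs flanked by consistent stretches is labeled MIA_RICH
  sym <- c(rep("CONSISTENT", 40), rep("MIA", 20), rep("CONSISTENT", 40))
  obs <- tibble::tibble(chrom = "1", pos = seq_along(sym) * 1000L, symbol = sym)
  dec <- viterbi_decode(obs)
  expect_true(all(dec$path$state[41:60] == "MIA_RICH"))
  expect_true(all(dec$path$state[c(1:38, 63:100)] == "GOOD"))
})

test_that("segments are contiguous, maximal, and cut at inter-site midpoints", {
  sym <- c(rep("CONSISTENT", 30), rep("ALLHET", 30), rep("CONSISTENT", 30))
  pos <- cumsum(rep(2000L, 90))
  dec <- viterbi_decode(tibble::tibble(chrom = "1", pos = pos, symbol = sym))
  seg <- dec$segments
  expect_gte(nrow(seg), 3)
  # contiguous over observed span, adjacent segments differ in state
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
  expect_equal(seg$start[1], pos[1] - 1L)
  expect_equal(seg$end[nrow(seg)], pos[length(pos)])
  # boundaries at midpoints between adjacent observed sites
  path <- dec$path
  switches <- which(diff(match(path$state, HMM_STATES)) != 0)
  for (s in switches) {
    mid <- (path$pos[s] + path$pos[s + 1]) %/% 2L
    expect_true(mid %in% seg$start)
  }
  # n_sites accounts for every observation
  expect_equal(sum(seg$n_sites), length(pos))
})

test_that("posterior decoding reports per-segment mean state confidence", {
  sym <- c(rep("CONSISTENT", 30), rep("MIA", 20), rep("CONSISTENT", 30))
  obs <- tibble::tibble(chrom = "1", pos = seq_along(sym) * 1500L, symbol = sym)
  dec <- viterbi_decode(obs, posterior = TRUE)
  expect_true(all(dec$segments$mean_posterior > 0.5))
  expect_true(all(dec$segments$mean_posterior <= 1))
})

test_that("doubling inter-site gaps does not add spurious state switches on planted data", {
  sim <- simulate_trio(trio_sim_spec(seed = 17))
  obs <- encode_trio_observations(sim$calls, "FATHER", "MOTHER", "CHILD")
  dense <- viterbi_decode(obs)
  sparse_obs <- dplyr::mutate(obs, pos = pos * 2L)
  sparse <- viterbi_decode(sparse_obs)
  n_switch <- function(d) sum(d$path$state[-1] != d$path$state[-nrow(d$path)])
  planted_boundaries <- nrow(sim$segments_truth) - length(unique(sim$segments_truth$chrom))
  expect_lte(n_switch(sparse), n_switch(dense) + planted_boundaries)
})

test_that("region filters soft-label without dropping records and tidy/glance/autoplot work", {
  sim <- simulate_trio(trio_sim_spec(seed = 2))
  obs <- encode_trio_observations(sim$calls, "FATHER", "MOTHER", "CHILD")
  dec <- viterbi_decode(obs)
  lab <- apply_region_filters(sim$calls, dec)
  expect_equal(nrow(lab), nrow(sim$calls))
  bad <- dplyr::filter(dec$segments, state != "GOOD")
  in_bad <- !is.na(varmend:::interval_lookup(lab$chrom, lab$pos, bad))
  expect_true(all(grepl("COMPRESSION|MIA_RICH", lab$filter[in_bad])))
  expect_true(all(lab$filter[!in_bad] == sim$calls$filter[!in_bad]))
  # records on contigs without segments stay untouched
  other <- tibble::tibble(chrom = "99", pos = 1L, filter = "PASS")
  expect_equal(apply_region_filters(other, dec)$filter, "PASS")
  # applying twice never duplicates a label
  twice <- apply_region_filters(lab, dec)
  expect_equal(twice$filter, lab$filter)
  expect_s3_class(tidy(dec), "tbl_df")
  expect_equal(glance(dec)$n_obs, nrow(obs))
  expect_s3_class(ggplot2::autoplot(dec), "ggplot")
})
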