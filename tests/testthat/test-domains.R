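# window p-score: frozen values from an exact binomial-tail oracle
# (explicit summation of choose(N,k) p^k (1-p)^(N-k); computed once and
# pinned).  Sites every 10 bp, window 20 bp => 3 sites per interior window.

test_that("window_pscore reproduces the exact binomial tail", {
  prof <- toy_profile()          # counts 0,0,0,9,9,9,0,0,0,0 ; N = 27
  tr <- window_pscore(prof, toy_fragmap(), window_bp = 20, scope = "cis",
                      mask_bait_sites = 0L)
  expect_equal(tr$window_sum, c(0, 0, 9, 18, 27, 18, 9, 0, 0, 0))
  expect_equal(tr$n_window_sites, c(2, 3, 3, 3, 3, 3, 3, 3, 3, 2))
  # oracle: P[Binom(27, 3/10) >= 18] and >= 27
  expect_equal(tr$p_value[4], 9.11090330080715e-05, tolerance = 1e-10)
  expect_equal(tr$p_value[5], 7.62559748498699e-15, tolerance = 1e-10)
  expect_equal(tr$p_score[5], -log10(0.3^27), tolerance = 1e-8)
  expect_equal(tr$p_value[c(1, 2, 8:10)], rep(1, 5))
  expect_equal(tr$p_score[c(1, 2, 8:10)], rep(0, 5))
})

test_that("uniform counts give equal interior p-scores; zero profile is null", {
  prof <- toy_profile(rep(2, 10))
  tr <- window_pscore(prof, toy_fragmap(), 20, "cis", mask_bait_sites = 0L)
  expect_equal(length(unique(tr$p_score[2:9])), 1L)

  expect_warning(
    tr0 <- window_pscore(toy_profile(rep(0, 10)), toy_fragmap(), 20, "cis",
                         mask_bait_sites = 0L),
    "zero reads")
  expect_equal(tr0$p_value, rep(1, 10))
  expect_equal(tr0$p_score, rep(0, 10))
})

test_that("cis and trans scopes partition the site grid", {
  fm <- make_fragmap(list(c1 = c(10, 20, 30), c2 = c(15, 30, 45)),
                     c(c1 = 50, c2 = 60))
  prof <- site_profile(fm, c(1, 2, 3, 4, 5, 6),
                       bait = list(chrom = "c1", pos = 25))
  cis <- window_pscore(prof, fm, 10, "cis", mask_bait_sites = 0L)
  # a window below the median site spacing (15 bp on c2) is warned about
  expect_warning(trans <- window_pscore(prof, fm, 10, "trans",
                                        mask_bait_sites = 0L), "spacing")
  expect_setequal(cis$chrom, "c1")
  expect_setequal(trans$chrom, "c2")
  expect_equal(attr(trans, "scope_reads"), 15)
  # bait masking blanks the two fragment-flanking sites
  cism <- suppressWarnings(
    window_pscore(prof, fm, 10, "cis", mask_bait_sites = 1L))
  expect_equal(cism$count[2:3], c(0, 0))
})

test_that("threshold_sites selects exactly the top fraction, ties excluded", {
  tr <- flag_track(rep(0, 1000))
  tr$p_score <- sample(seq_len(1000))   # distinct
  th <- threshold_sites(tr, 0.10)
  expect_equal(sum(th$positive), 100L)
  expect_true(all(th$p_score[th$positive] > attr(th, "cutoff")))

  th2 <- threshold_sites(tr, 0.999)
  expect_equal(sum(th2$positive), 999L)  # all but the minimum

  tied <- flag_track(rep(0, 100))
  tied$p_score <- rep(7, 100)
  expect_warning(th3 <- threshold_sites(tied, 0.05), "degenerate")
  expect_equal(sum(th3$positive), 0L)

  expect_error(threshold_sites(tr, 1.5), "top_frac")
})

test_that("raising top_frac never shrinks the positive set", {
  set.seed(5)
  tr <- flag_track(rep(0, 500))
  tr$p_score <- rnorm(500)
  prev <- rep(FALSE, 500)
  for (tf in c(0.02, 0.05, 0.10, 0.25, 0.5)) {
    cur <- threshold_sites(tr, tf)$positive
    expect_true(all(cur[prev]))          # superset property
    prev <- cur
  }
})

test_that("call_domains equals brute-force run enumeration on random flags", {
  set.seed(9)
  flags <- runif(10000) < 0.1
  tr <- flag_track(flags)
  fm <- make_fragmap(list(t1 = tr$pos), c(t1 = max(tr$pos) + 10))
  for (mr in c(1L, 3L, 16L)) {
    got <- call_domains(tr, fm, min_run = mr)
    want <- brute_force_domains(flags, tr$pos, mr)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_positive_sites, as.integer(want$n))
  }
})

test_that("'more than 15 consecutive' excludes runs of exactly 15", {
  flags <- c(rep(TRUE, 15), FALSE, rep(TRUE, 16), FALSE, rep(TRUE, 40))
  tr <- flag_track(flags)
  fm <- make_fragmap(list(t1 = tr$pos), c(t1 = max(tr$pos) + 10))
  doms <- call_domains(tr, fm, min_run = 16L)
  expect_equal(nrow(doms), 2L)
  expect_equal(doms$n_positive_sites, c(16L, 40L))

  none <- call_domains(flag_track(rep(FALSE, 100)), fm, 16L)
  expect_equal(nrow(none), 0L)
})

test_that("runs are broken at chromosome boundaries", {
  fm <- make_fragmap(list(a = (1:10) * 10, b = (1:10) * 10),
                     c(a = 200, b = 200))
  tr <- structure(
    data.frame(chrom = rep(c("a", "b"), each = 10),
               pos = rep((1:10) * 10, 2), p_score = 1,
               positive = TRUE),
    scope = "cis", class = c("WindowScoreTrack", "data.frame"))
  doms <- call_domains(tr, fm, min_run = 10L)
  expect_equal(nrow(doms), 2L)   # one per chromosome, never spliced
})

test_that("estimate_fdr behaves at the null and validates inputs", {
  fm <- toy_fragmap()
  prof <- toy_profile(rep(3, 10))
  expect_error(estimate_fdr(prof, fm, 20, "cis", 0.10, n_permutations = 0),
               ">= 10")
  # all-equal scores: zero positives -> NA, not 0
  expect_message(
    r <- suppressWarnings(
      estimate_fdr(prof, fm, 20, "cis", 0.10, 10, seed = 1,
                   mask_bait_sites = 0L)),
    "not applicable")
  expect_true(is.na(r$fdr))
})

test_that("sliding_window_counts tiles, conserves and localizes reads", {
  fm <- make_fragmap(list(c1 = seq(5000, 195000, by = 5000)),
                     c(c1 = 2e5))
  cnt <- rep(0, n_sites(fm))
  cnt[fm$sites$pos == 60000] <- 1
  prof <- site_profile(fm, cnt, bait = list(chrom = "c1", pos = 0))
  sw <- sliding_window_counts(prof, fm, window_bp = 5e4, step_bp = 2.5e4)
  expect_equal(sum(sw$count == 1), 2L)   # ceiling(window/step) = 2 windows
  expect_equal(sum(sw$count), 2)
  # conservation over the non-overlapping alternate window set
  prof2 <- site_profile(fm, rep(2, n_sites(fm)),
                        bait = list(chrom = "c1", pos = 0))
  sw2 <- sliding_window_counts(prof2, fm, 5e4, 2.5e4)
  expect_equal(sum(sw2$count[sw2$start %% 5e4 == 0]),
               attr(prof2, "library_size"))
  # empty profile
  sw0 <- sliding_window_counts(toy_profile(rep(0, 10)), toy_fragmap(),
                               50, 25)
  expect_true(all(sw0$count == 0))
  expect_error(sliding_window_counts(prof, fm, 100, 200), "step_bp")
})

test_that("domain recovery metrics score coverage and respect exclusions", {
  truth <- data.frame(chrom = "c", start = c(100, 500), end = c(200, 600))
  called <- data.frame(chrom = "c", start = c(90, 800), end = c(210, 900))
  r <- domain_recovery(called, truth)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$precision, 0.5)
  # excluded called domains do not hurt precision but still give coverage
  r2 <- domain_recovery(called, truth,
                        exclude = data.frame(chrom = "c", start = 700,
                                             end = 1000))
  expect_equal(r2$sensitivity, 0.5)
  expect_equal(r2$precision, 1)
})
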