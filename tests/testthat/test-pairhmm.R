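# Profile pair-HMM: emission model, forward-backward posteriors against the
# exhaustive path-enumeration oracle, constraint extraction.

test_that("parameter set satisfies its invariants", {
  p <- pairhmm_params()
  # outgoing transition mass sums to 1 for every state
  expect_equal(1 - 2 * p$gap_open_short - 2 * p$gap_open_long +
                 2 * p$gap_open_short + 2 * p$gap_open_long, 1)
  expect_equal(sum(p$emission), 1, tolerance = 1e-6)
  expect_true(all(p$emission > 0))
  expect_equal(p$emission, t(p$emission), tolerance = 1e-9)
  expect_equal(sum(p$background), 1, tolerance = 1e-9)
  expect_error(pairhmm_params(gap_open_short = 0.3, gap_open_long = 0.3),
               "gap-open")
})

test_that("point-mass emission reduces to the sequence likelihood ratio", {
  p <- pairhmm_params()
  colA <- colB <- rep(0, 21)
  colA[1] <- 1              # A
  colB[2] <- 1              # R
  expect_equal(column_emission_score(colA, colB, p),
               unname(p$emission[1, 2] / (p$background[1] * p$background[2])),
               tolerance = 1e-12)
  # symmetry for arbitrary columns
  withr::local_seed(1)
  for (k in 1:5) {
    a <- stats::runif(21); a <- a / sum(a)
    b <- stats::runif(21); b <- b / sum(b)
    expect_equal(column_emission_score(a, b, p),
                 column_emission_score(b, a, p), tolerance = 1e-12)
  }
})

test_that("emission equals the explicit 20x20 double sum", {
  p <- pairhmm_params()
  u <- c(rep(1 / 20, 20), 0)
  byhand <- 0
  for (a in 1:20) {
    for (b in 1:20) {
      byhand <- byhand + (1 / 400) * p$emission[a, b] /
        (p$background[a] * p$background[b])
    }
  }
  expect_equal(column_emission_score(u, u, p), unname(byhand),
               tolerance = 1e-12)
})

test_that("length-1 posteriors match exhaustive path enumeration", {
  p <- pairhmm_params()
  pa <- profile_from_sequence(c(a = "L"))
  pb <- profile_from_sequence(c(b = "L"))
  fb <- forward_backward(pa, pb, p)
  orc <- oracle_posteriors(pa$freq, pb$freq, p)
  expect_equal(fb$posterior[1, 1], orc$posterior[1, 1], tolerance = 1e-9)
  expect_equal(exp(fb$loglik_forward), orc$total, tolerance = 1e-9)
})

test_that("posteriors equal the enumeration oracle for short profiles", {
  p <- pairhmm_params()
  withr::local_seed(11)
  for (k in 1:20) {
    pa <- random_profile(sample(1:3, 1), k = 3, gap = k %% 2 == 0)
    pb <- random_profile(sample(1:3, 1), k = 3, gap = k %% 2 == 0)
    fb <- forward_backward(pa, pb, p)
    orc <- oracle_posteriors(pa$freq, pb$freq, p)
    expect_equal(fb$posterior, orc$posterior, tolerance = 1e-9)
  }
})

test_that("forward and backward totals agree for long random profiles", {
  p <- pairhmm_params()
  withr::local_seed(21)
  for (len in c(50, 200)) {
    pa <- random_profile(len, k = 20, gap = TRUE)
    pb <- random_profile(len - 7, k = 20, gap = TRUE)
    fb <- forward_backward(pa, pb, p)
    expect_true(is.finite(fb$loglik_forward))
    expect_equal(fb$loglik_forward, fb$loglik_backward,
                 tolerance = 1e-6)
    expect_true(all(fb$posterior >= 0 & fb$posterior <= 1))
    expect_true(all(rowSums(fb$posterior) <= 1 + 1e-6))
    expect_true(all(colSums(fb$posterior) <= 1 + 1e-6))
  }
})

test_that("swapping the profiles transposes the posterior matrix", {
  p <- pairhmm_params()
  pa <- profile_from_sequence(c(a = "MKTLIVFG"))
  pb <- profile_from_sequence(c(b = "MKTLWG"))
  f1 <- forward_backward(pa, pb, p)
  f2 <- forward_backward(pb, pa, p)
  expect_equal(f1$posterior, t(f2$posterior), tolerance = 1e-9)
})

test_that("profile mode on self-profiles equals plain sequence mode", {
  # a degenerate (point-mass) profile is exactly the sequence case: the same
  # posteriors must come out whether columns were built from hits or not
  p <- pairhmm_params()
  s1 <- "MKTLIVFGWA"; s2 <- "MKTLCVFGWA"
  pa <- profile_from_sequence(c(a = s1))
  # hand-built point-mass profile, bypassing build_profile
  freq <- matrix(0, 21, nchar(s2),
                 dimnames = list(tmcoffee:::PROFILE_ALPHABET, NULL))
  for (i in seq_len(nchar(s2))) freq[substr(s2, i, i), i] <- 1
  pb_manual <- structure(list(query = NULL, freq = freq,
                              support = rep(1L, nchar(s2)), nhits = 0L),
                         class = "tmc_profile")
  pb <- profile_from_sequence(c(b = s2))
  expect_equal(forward_backward(pa, pb, p)$posterior,
               forward_backward(pa, pb_manual, p)$posterior,
               tolerance = 1e-12)
})

test_that("identical profiles put their confidence on the diagonal", {
  p <- pairhmm_params()
  pa <- profile_from_sequence(c(a = "MKWTLIV"))
  pb <- profile_from_sequence(c(b = "MKWTLIV"))
  post <- forward_backward(pa, pb, p)$posterior
  for (i in seq_len(nrow(post))) {
    expect_true(all(post[i, i] > post[i, -i]))
  }
})

test_that("extract_constraints thresholds strictly and rounds half up", {
  post <- matrix(0, 2, 2)
  post[1, 1] <- 0.995
  cons <- extract_constraints(post, "a", "b")
  expect_equal(nrow(cons), 1)
  expect_equal(cons$weight, 100)  # round(99.5) half up
  post[1, 1] <- 0.99
  expect_equal(nrow(extract_constraints(post, "a", "b")), 0)  # strict >
  post[1, 1] <- 0.98
  expect_equal(nrow(extract_constraints(post, "a", "b")), 0)
  expect_error(extract_constraints(post, "a", "b", threshold = 0), "threshold")
  expect_error(extract_constraints(post, "a", "b", threshold = 1.2), "threshold")
})

test_that("parameter config files round-trip through read_pairhmm_params", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# pair-HMM parameters", "gap_open_short = 0.02",
               "gap_extend_short = 0.4", "occupancy = 0"), f)
  p <- read_pairhmm_params(f)
  expect_equal(p$gap_open_short, 0.02)
  expect_equal(p$gap_extend_short, 0.4)
  expect_false(p$occupancy)
  writeLines("not_a_key = 1", f)
  expect_error(read_pairhmm_params(f), "unknown parameter")
})
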