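# Cardinality estimators: corrected harmonic mean, secant MLE, joint MLE.

test_that("harmonic-mean estimator follows the printed formula and linear counting", {
  expect_identical(estimate_original(hll_sketch(p = 10)), 0)

  # m = 16, all registers 1: E = (1/(2 ln 2)) * 256 / (16 * 2^-1), C_0 = 0
  sk <- hll_sketch(p = 4)
  sk$registers <- as.raw(rep(1, 16))
  expect_equal(estimate_original(sk), 256 / (2 * log(2) * 8), tolerance = 1e-12)

  # low load switches to linear counting m * ln(m / C_0)
  one <- hll_insert(hll_sketch(p = 10), as_hex64(99))
  expect_equal(estimate_original(one), 1024 * log(1024 / 1023), tolerance = 1e-12)
})

test_that("register-value probabilities telescope to one", {
  q <- 54L
  for (z in c(1e-6, 0.5, 3, 700, 1e6)) {
    # exp of the one-hot log-likelihoods recovers P_z(v)
    P <- vapply(0:(q + 1L), function(v) {
      hist <- integer(q + 2L)
      hist[v + 1L] <- 1L
      exp(mle_log_likelihood(z, hist, q))
    }, numeric(1))
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("log-likelihood is unimodal in the rate for model histograms", {
  set.seed(31)
  for (n in c(50, 5e3, 5e5)) {
    sk <- rand_hll(n, p = 8, seed = 31, stream = n)
    hist <- register_histogram(sk)
    zgrid <- exp(seq(log(n / 256 / 50), log(n / 256 * 50), length.out = 300))
    L <- vapply(zgrid, mle_log_likelihood, numeric(1), hist = hist, q = sk$q)
    d <- diff(L) > 0
    expect_identical(sum(diff(d) != 0), 1L)  # rises then falls, one turn
  }
})

test_that("secant MLE agrees with a golden-section oracle across scales", {
  cards <- round(10^seq(1, 7, length.out = 30))
  cases <- expand.grid(n = cards, p = c(8L, 12L))
  for (i in seq_len(nrow(cases))) {
    sk <- rand_hll(cases$n[i], p = cases$p[i], seed = 32, stream = i)
    est <- estimate_mle(sk)
    expect_equal(as.numeric(est), mle_oracle(sk), tolerance = 1e-6)
    expect_lte(attr(est, "iterations"), 3L)
  }
})

test_that("MLE endpoints: empty -> 0, saturated -> infinity signal", {
  e <- estimate_mle(hll_sketch(p = 8))
  expect_identical(as.numeric(e), 0)
  expect_identical(attr(e, "iterations"), 0L)

  sat <- hll_sketch(p = 8)
  sat$registers <- as.raw(rep(sat$q + 1L, sat$m))
  expect_identical(as.numeric(estimate_mle(sat)), Inf)
})

test_that("both estimators are monotone in the registers", {
  set.seed(33)
  sk <- rand_hll(2e4, p = 8, seed = 33)
  for (i in 1:20) {
    bumped <- sk
    j <- sample(sk$m, 1)
    v <- as.integer(bumped$registers[j])
    bumped$registers[j] <- as.raw(min(v + sample(3, 1), sk$q + 1L))
    expect_gte(estimate_original(bumped), estimate_original(sk))
    expect_gte(as.numeric(estimate_mle(bumped)), as.numeric(estimate_mle(sk)))
  }
})

test_that("median relative error stays within 2% across the scale sweep", {
  for (n in 10^(2:6)) {
    rel <- vapply(1:10, function(t) {
      sk <- rand_hll(n, p = 14, seed = 34, stream = n + t)
      c(abs(estimate_original(sk) / n - 1), abs(as.numeric(estimate_mle(sk)) / n - 1))
    }, numeric(2))
    expect_lt(median(rel[1, ]), 0.02)
    expect_lt(median(rel[2, ]), 0.02)
  }
})

test_that("joint likelihood factorizes at zero shared rate and matches per-register accumulation", {
  set.seed(35)
  a <- hll_insert(hll_sketch(p = 4), rand_hex(40))
  b <- hll_insert(hll_sketch(p = 4), rand_hex(40))
  tally <- joint_register_tally(a, b)
  m <- a$m; q <- a$q

  la <- 35; lb <- 45
  expect_equal(joint_log_likelihood(c(la, lb, 0), tally, m, q),
               mle_log_likelihood(la / m, register_histogram(a), q) +
                 mle_log_likelihood(lb / m, register_histogram(b), q),
               tolerance = 1e-10)

  # tally accumulation equals the direct per-register sum
  direct <- 0
  for (j in seq_len(m)) {
    one <- matrix(0L, q + 2L, q + 2L)
    one[as.integer(a$registers[j]) + 1L, as.integer(b$registers[j]) + 1L] <- 1L
    direct <- direct + joint_log_likelihood(c(30, 50, 20), one, m, q)
  }
  expect_equal(joint_log_likelihood(c(30, 50, 20), tally, m, q), direct,
               tolerance = 1e-10)

  # identical registers prefer all mass on the shared component
  u <- hll_union(a, b)
  tu <- joint_register_tally(u, u)
  nu <- as.numeric(estimate_mle(u))
  expect_gt(joint_log_likelihood(c(0, 0, nu), tu, m, q),
            joint_log_likelihood(c(nu / 2, nu / 2, nu / 2), tu, m, q))
})

test_that("joint MLE recovers the three components of simulated pairs", {
  # identical sketches: no unique mass, Jaccard ~ 1
  sk <- rand_hll(1e5, p = 12, seed = 36)
  jm <- estimate_jmle(sk, sk)
  expect_gte(jm$jaccard, 0.99)
  expect_lt(jm$lambda_a + jm$lambda_b, 0.02 * jm$lambda_x)
  expect_equal(jm$lambda_x, as.numeric(estimate_mle(sk)), tolerance = 0.02)

  # disjoint sets of 1e5: implied Jaccard near 0
  low <- vapply(1:10, function(t) {
    tr <- kmersketch:::cpp_pair_trial(1e5, 1e5, 0, 36, t, 12L, integer(0))
    a <- hll_sketch(p = 12); a$registers <- tr$hll_a[[1]]
    b <- hll_sketch(p = 12); b$registers <- tr$hll_b[[1]]
    estimate_jmle(a, b)$jaccard
  }, numeric(1))
  expect_true(mean(low < 0.01) >= 0.9)

  # joint estimate agrees with the dense grid-refinement oracle
  for (t in 1:6) {
    tr <- kmersketch:::cpp_pair_trial(3000, 2000, 1000, 37, t, 8L, integer(0))
    a <- hll_sketch(p = 8); a$registers <- tr$hll_a[[1]]
    b <- hll_sketch(p = 8); b$registers <- tr$hll_b[[1]]
    jm <- estimate_jmle(a, b)
    oracle <- jmle_grid_oracle(a, b)
    expect_equal(c(jm$lambda_a, jm$lambda_b, jm$lambda_x), oracle,
                 tolerance = 1e-3)
    expect_true(jm$jaccard >= 0 && jm$jaccard <= 1)
  }
})

test_that("inclusion-exclusion collapses exactly for identical sketches and never goes negative", {
  sk <- rand_hll(5e4, p = 10, seed = 38)
  expect_equal(intersection_inclusion_exclusion(sk, sk, "mle"),
               as.numeric(estimate_mle(sk)), tolerance = 1e-12)
  expect_equal(intersection_inclusion_exclusion(sk, sk, "original"),
               estimate_original(sk), tolerance = 1e-12)

  for (t in 1:10) {
    tr <- kmersketch:::cpp_pair_trial(1e4, 1e4, 0, 38, t, 10L, integer(0))
    a <- hll_sketch(p = 10); a$registers <- tr$hll_a[[1]]
    b <- hll_sketch(p = 10); b$registers <- tr$hll_b[[1]]
    inter <- intersection_inclusion_exclusion(a, b)
    expect_gte(inter, 0)
    # disjoint sets: |result| within 3 combined standard errors of 0
    se <- 1.03896 / sqrt(1024) * 1e4 * sqrt(3)
    expect_lte(inter, 3 * se)
  }
})
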