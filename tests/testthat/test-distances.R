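# Pair statistics, Mash distance, all-pairs tables, exact hash-set mode.

test_that("Mash distance transform matches the standard formula", {
  expect_equal(mash_distance(1, 21), 0)
  expect_equal(mash_distance(0.5, 21), -(1 / 21) * log(2 / 3), tolerance = 1e-12)
  expect_equal(mash_distance(0, 21), 1)  # declared cap at J = 0
  j <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(mash_distance(j, 31)) < 0))  # monotone decreasing
})

test_that("identical sketches give unit similarity under every estimator", {
  sk <- rand_hll(2e4, p = 10, seed = 51)
  for (est in c("original", "mle", "jmle")) {
    ps <- pair_statistics(sk, sk, estimator = est)
    expect_equal(ps$jaccard, 1)
    expect_equal(ps$containment, 1)
    expect_equal(ps$overlap, 1)
    expect_equal(ps$mash_distance, 0)
  }
})

test_that("unequal set sizes cap the estimated Jaccard near 1/c", {
  ratio <- 16
  js <- vapply(1:10, function(t) {
    tr <- kmersketch:::cpp_pair_trial(16 * 1e4, 1e4, 1e4, 51, t, 12L, integer(0))
    a <- hll_sketch(p = 12); a$registers <- tr$hll_a[[1]]
    b <- hll_sketch(p = 12); b$registers <- tr$hll_b[[1]]
    pair_statistics(a, b)$jaccard
  }, numeric(1))
  # true J here is its maximum 1/c; estimates stay below 1/c + 3 sigma
  sigma <- 3 * 1.03896 / sqrt(4096)
  expect_true(all(js <= 1 / ratio + 3 * sigma))
})

test_that("exact mode performs true hash-set arithmetic", {
  td <- withr::local_tempdir()
  set.seed(52)
  s1 <- rand_dna(10000)
  ps_self <- exact_jaccard(write_fasta(file.path(td, "a.fa"), s1),
                           file.path(td, "a.fa"), k = 31)
  expect_equal(ps_self$jaccard, 1)

  # strand symmetry: a sequence and its reverse complement share all k-mers
  write_fasta(file.path(td, "rc.fa"), revcomp_str(s1))
  expect_equal(exact_jaccard(file.path(td, "a.fa"), file.path(td, "rc.fa"),
                             k = 31)$jaccard, 1)

  # planted 5-kb block: agree exactly with an independent R set computation
  shared <- rand_dna(5000)
  sa <- paste0(rand_dna(5000), shared)
  sb <- paste0(shared, rand_dna(5000))
  write_fasta(file.path(td, "sa.fa"), sa)
  write_fasta(file.path(td, "sb.fa"), sb)
  ps <- exact_jaccard(file.path(td, "sa.fa"), file.path(td, "sb.fa"), k = 31)

  kset <- function(s, k = 31) {
    w <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- vapply(w, revcomp_str, character(1), USE.NAMES = FALSE)
    unique(pmin(w, rc))  # A<C<G<T is the lexicographic order of the codes
  }
  A <- kset(sa); B <- kset(sb)
  expect_identical(ps$card_a, as.numeric(length(A)))
  expect_identical(ps$card_b, as.numeric(length(B)))
  expect_identical(ps$card_intersection, as.numeric(length(intersect(A, B))))
  expect_equal(ps$jaccard, length(intersect(A, B)) / length(union(A, B)),
               tolerance = 1e-15)
})

test_that("all_pairs emits the ordered triangle and is label-permutation invariant", {
  set.seed(53)
  sks <- lapply(1:4, function(i) rand_hll(5e3, p = 8, seed = 53, stream = i))
  names(sks) <- paste0("s", 1:4)
  ap <- all_pairs(sks)
  expect_identical(nrow(ap), 6L)
  expect_identical(ap$query, c("s1", "s1", "s1", "s2", "s2", "s3"))
  expect_true(all(ap$jaccard >= 0 & ap$jaccard <= 1))

  perm <- all_pairs(sks[c(3, 1, 4, 2)])
  key <- function(d) {
    k <- apply(cbind(d$query, d$reference), 1, function(r) paste(sort(r), collapse = "|"))
    d$jaccard[order(k)]
  }
  expect_equal(key(perm), key(ap))

  # symmetry of J, asymmetry of containment
  ab <- pair_statistics(sks[[1]], sks[[2]])
  ba <- pair_statistics(sks[[2]], sks[[1]])
  expect_equal(ab$jaccard, ba$jaccard)
  expect_equal(ab$card_intersection / ab$card_a, ab$containment, tolerance = 1e-12)

  bad <- c(sks, list(other = rand_hll(100, p = 10)))
  expect_error(all_pairs(bad), class = "kmersketch_incompatible")
  expect_error(all_pairs(bad), "other")
})

test_that("sketched Jaccard converges to the exact value as registers grow", {
  med_err <- vapply(c(8L, 10L, 12L, 14L), function(p) {
    errs <- vapply(1:8, function(t) {
      tr <- kmersketch:::cpp_pair_trial(2e4, 2e4, 1e4, 54, t, p, integer(0))
      a <- hll_sketch(p = p); a$registers <- tr$hll_a[[1]]
      b <- hll_sketch(p = p); b$registers <- tr$hll_b[[1]]
      abs(pair_statistics(a, b)$jaccard - 1 / 3)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})
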