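# Synthetic-set harness: pair construction, accuracy experiment, RSE and
# iteration-census commands.

test_that("intersection sizing follows i = J(|A|+|B|)/(1+J) with feasibility guard", {
  n <- 1200
  expect_identical(intersection_for_jaccard(n, n, 1 / 3), n / 2)
  expect_error(intersection_for_jaccard(4000, 1000, 0.5),
               class = "kmersketch_infeasible")
  expect_error(intersection_for_jaccard(4000, 1000, 0.5), "1/c|1 / c")
  # a named cell: ratio 2^3 with J fixed at 0.111 is feasible
  expect_lte(intersection_for_jaccard(2^15, 2^12, 0.111), 2^12)
})

test_that("generated pairs hit the planted intersection exactly", {
  for (t in 1:5) {
    mp <- make_set_pair(2000, 500, 0.11, seed = t)
    expect_length(mp$a, 2000L)
    expect_length(mp$b, 500L)
    expect_identical(length(intersect(mp$a, mp$b)), as.integer(mp$intersection))
    expect_identical(anyDuplicated(mp$a), 0L)
    expect_identical(anyDuplicated(mp$b), 0L)
    expect_equal(mp$jaccard, length(intersect(mp$a, mp$b)) /
                   length(union(mp$a, mp$b)))
  }
  # reproducible from the seed, distinct across seeds
  expect_identical(make_set_pair(300, 300, 0.2, seed = 9),
                   make_set_pair(300, 300, 0.2, seed = 9))
  expect_false(identical(make_set_pair(300, 300, 0.2, seed = 9)$a,
                         make_set_pair(300, 300, 0.2, seed = 10)$a))
})

test_that("the default grid reconstructs 36 feasible study cells", {
  g <- accuracy_grid()
  expect_identical(nrow(g), 36L)
  expect_true(all(g$intersection <= pmin(g$size_a, g$size_b)))
  expect_true(all(abs(g$true_j - g$target_j) < 0.05 * pmax(g$target_j, 0.01)))
  # the J <= 1/c bound is what prunes the infeasible combinations
  expect_true(all(g$true_j <= g$size_b / g$size_a + 1e-9))
})

test_that("accuracy experiment is seed-reproducible and the exact oracle has zero error", {
  g <- accuracy_grid(size_log2 = 14L, ratio_log2 = c(0L, 3L),
                     target_j = c(0.111, 0.6))
  r1 <- accuracy_experiment(grid = g, sketch_log2_bytes = c(10L, 12L),
                            trials = 3L, seed = 5L)
  r2 <- accuracy_experiment(grid = g, sketch_log2_bytes = c(10L, 12L),
                            trials = 3L, seed = 5L)
  expect_identical(r1, r2)

  ex <- accuracy_experiment(grid = g[g$size_a + g$size_b <= 2^21, ],
                            sketch_log2_bytes = 10L, methods = "exact",
                            trials = 2L, seed = 5L)
  expect_true(all(ex$max_abs_error == 0))
})

test_that("HLL error shrinks with sketch size and beats MinHash on unequal sets", {
  g <- accuracy_grid(size_log2 = 18L)
  res <- accuracy_experiment(grid = g, trials = 10L, seed = 6L)

  # Monotone improvement with sketch size for the fixed-J equal-size cells
  for (j in unique(g$target_j[g$size_a == g$size_b])) {
    hll <- res[res$method == "hll" & res$target_j == j &
                 res$size_a == res$size_b, ]
    hll <- hll[order(hll$log2_bytes), ]
    expect_true(all(diff(hll$mean_abs_error) < 0))
  }

  # 1-kB sketches, size ratio >= 2^3: HLL mean error below MinHash
  sub <- res[res$log2_bytes == 10 & res$size_a / res$size_b >= 8, ]
  cmp <- tapply(sub$mean_abs_error, sub$method, mean)
  expect_lt(cmp[["hll"]], cmp[["minhash"]])
})

test_that("RSE experiment enforces the trial floor and the 1/sqrt(m) scaling", {
  expect_error(rse_constant_experiment(trials = 10L),
               class = "kmersketch_format")
  res <- rse_constant_experiment(p = c(8L, 9L), n = 2e4, trials = 150L, seed = 7L)
  # doubling m halves the squared RSE, within generous Monte-Carlo bounds
  ratio <- res$rse[res$p == 8L]^2 / res$rse[res$p == 9L]^2
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
  expect_equal(attr(res, "constant"), mean(res$rse_sqrt_m))
})

test_that("the bench command writes its table as CSV", {
  out <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(cli_main(c("bench", "rse", "--trials", "30",
                              "--seed", "3", "--out", out)))
  tab <- read.csv(out)
  expect_identical(names(tab), c("p", "m", "rse", "rse_sqrt_m"))
  expect_identical(tab$m, 1024L)
  expect_error(suppressMessages(cli_main(c("bench", "nope"))),
               class = "kmersketch_format")
})

test_that("the iteration census is reproducible from its seed", {
  cards <- round(10^seq(1, 5, length.out = 10))
  c1 <- secant_iteration_census(cardinalities = cards, p = c(8L, 12L),
                                reps = 2L, seed = 8L)
  c2 <- secant_iteration_census(cardinalities = cards, p = c(8L, 12L),
                                reps = 2L, seed = 8L)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$max_iterations, max(c1$table$iterations))
})
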