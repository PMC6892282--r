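# Shared fixtures: random hex64 values, random sketches, tiny sequence
# files — all generated in code under the caller's seed.

rand_hex <- function(n) {
  vapply(seq_len(n),
         function(i) paste(sample(c(0:9, letters[1:6]), 16, TRUE), collapse = ""),
         character(1))
}

# HLL sketch filled with n distinct random 64-bit values via the Wang path
rand_hll <- function(n, p = 10L, seed = 1L, stream = 1L) {
  sk <- hll_sketch(p = p)
  sk$registers <- kmersketch:::cpp_random_hll(n, seed, stream, as.integer(p))
  sk
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

write_fasta <- function(path, seqs) {
  writeLines(unlist(lapply(seq_along(seqs),
                           function(i) c(paste0(">seq", i), seqs[i]))), path)
  path
}

write_fastq <- function(path, seqs) {
  writeLines(unlist(lapply(seq_along(seqs), function(i) {
    c(paste0("@read", i), seqs[i], "+", strrep("I", nchar(seqs[i])))
  })), path)
  path
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# independent golden-section oracle for the marginal MLE: maximize the
# log-likelihood over log(z) directly
mle_oracle <- function(sketch) {
  hist <- register_histogram(sketch)
  q <- sketch$q
  m <- sketch$m
  f <- function(lz) mle_log_likelihood(exp(lz), hist, q)
  opt <- optimize(f, c(log(1e-8), log(2^40)), maximum = TRUE, tol = 1e-12)
  m * exp(opt$maximum)
}

# independent dense-grid refinement oracle for the joint MLE
jmle_grid_oracle <- function(a, b, rounds = 6L, steps = 9L) {
  tally <- joint_register_tally(a, b)
  m <- a$m; q <- a$q
  est_a <- as.numeric(estimate_mle(a))
  est_b <- as.numeric(estimate_mle(b))
  est_u <- as.numeric(estimate_mle(hll_union(a, b)))
  lx <- max(est_a + est_b - est_u, est_u * 1e-3)
  center <- pmax(c(est_a - lx, est_b - lx, lx), est_u * 1e-3)
  f <- 4
  for (r in seq_len(rounds)) {
    fac <- exp(seq(-log(f), log(f), length.out = steps))
    grid <- expand.grid(la = center[1] * fac, lb = center[2] * fac,
                        lx = center[3] * fac)
    ll <- vapply(seq_len(nrow(grid)), function(i)
      joint_log_likelihood(as.numeric(grid[i, ]), tally, m, q), numeric(1))
    center <- as.numeric(grid[which.max(ll), ])
    f <- f^(2 / (steps - 1))
  }
  center
}
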