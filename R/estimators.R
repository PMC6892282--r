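# Cardinality estimation from HLL registers.
#
# The Poisson model: with n items spread over m registers, the number
# routed to one register is ~ Poisson(z), z = n/m, and the register value
# V satisfies P(V <= v) = exp(-z * phi(v)) with tail weight phi(v) = 2^-v
# for 0 <= v <= q and phi(q+1) = 0. The three estimators below are the
# corrected harmonic mean, the marginal MLE for z (solved with the secant
# method on the score function), and the joint MLE over a three-component
# mixture (A-only, B-only, shared) that estimates intersection cardinality
# directly from a pair of register arrays.

ALPHA_HM <- 1 / (2 * log(2))  # correction factor for the harmonic-mean estimator

#' Corrected harmonic-mean cardinality estimate
#'
#' E = alpha * m^2 / sum_j 2^(-M_j) with alpha = 1/(2 ln 2), where M_j is
#' the stored register value (1 + the maximum suffix LZC; 0 for an empty
#' register). When E <= 2.5 m and some registers are still empty, linear
#' counting m * ln(m / C_0) is returned instead, which is far more accurate
#' at low load. Deterministic given the registers.
#'
#' @param sketch an `hll_sketch`.
#' @return estimated cardinality (double, >= 0).
#' @export
estimate_original <- function(sketch) {
  hist <- register_histogram(sketch)
  m <- sketch$m
  v <- 0:(sketch$q + 1L)
  E <- ALPHA_HM * m^2 / sum(hist * 2^-v)
  C0 <- hist[[1L]]
  if (E <= 2.5 * m && C0 > 0L) m * log(m / C0) else E
}

#' Poisson log-likelihood of a register histogram
#'
#' L(z) = sum_v C_v log P_z(v) with P_z(0) = exp(-z),
#' P_z(v) = exp(-z 2^-v) - exp(-z 2^-(v-1)) for 1 <= v <= q, and
#' P_z(q+1) = 1 - exp(-z 2^-q). The P_z(v) telescope to 1 for every z >= 0.
#'
#' @param z Poisson rate per register (cardinality / m), >= 0.
#' @param hist register histogram C_0..C_(q+1) (see [register_histogram()]).
#' @param q suffix width of the sketch the histogram came from.
#' @return log-likelihood (double; -Inf where an observed value has zero
#'   probability, e.g. non-empty registers at z = 0).
#' @export
mle_log_likelihood <- function(z, hist, q) {
  stopifnot(length(hist) == q + 2L, z >= 0)
  v <- 1:q
  t <- 2^-v
  # P_v = u (1 - u) with u = exp(-z t), since exp(-z 2^-(v-1)) = u^2
  log1mu <- function(zt) log(-expm1(-zt))   # log(1 - exp(-zt)), stable
  terms <- numeric(q + 2L)
  terms[1L] <- -z                                  # v = 0
  terms[v + 1L] <- -z * t + log1mu(z * t)          # 1 <= v <= q
  terms[q + 2L] <- log1mu(z * 2^-q)                # v = q + 1 (saturated)
  used <- hist > 0L
  if (z == 0) terms[!is.finite(terms)] <- -Inf
  sum(hist[used] * terms[used])
}

# Score function dL/dz and its histogram-weighted evaluation.
mle_score <- function(z, hist, q) {
  v <- 1:q
  t <- 2^-v
  u <- exp(-z * t)
  onemu <- -expm1(-z * t)
  d <- numeric(q + 2L)
  d[1L] <- -1
  d[v + 1L] <- t * (2 * u - 1) / onemu
  uq <- exp(-z * 2^-q)
  d[q + 2L] <- 2^-q * uq / -expm1(-z * 2^-q)
  sum(hist * d)
}

#' Maximum-likelihood cardinality estimate (secant method)
#'
#' Maximizes the Poisson log-likelihood of the register histogram by
#' finding the root of its derivative with the secant method. The iteration
#' runs in the reciprocal-rate coordinate x = 1/z, where the score function
#' is close to linear over the plausible range, and is initialized from the
#' harmonic-mean estimate; a bisection bracket guards any step that leaves
#' the feasible region. Convergence is declared when a step moves the rate
#' by less than a relative 1e-9 (hard cap 64 iterations).
#'
#' An empty sketch yields 0 with 0 iterations. A saturated sketch (every
#' register at q + 1) carries no finite information and yields `Inf` rather
#' than a silently huge number.
#'
#' @param sketch an `hll_sketch`.
#' @return estimated cardinality, with attribute `"iterations"`: the number
#'   of secant updates needed to converge, i.e. the first update whose
#'   iterate lies within the relative tolerance of the converged value (the
#'   solver spends one further update detecting that no motion remains).
#' @export
estimate_mle <- function(sketch) {
  hist <- register_histogram(sketch)
  m <- sketch$m
  q <- sketch$q
  if (hist[[1L]] == m) return(structure(0, iterations = 0L))
  if (hist[[q + 2L]] == m) return(structure(Inf, iterations = 0L))

  z0 <- max(estimate_original(sketch) / m, 1e-12)
  g <- function(x) mle_score(1 / x, hist, q)  # increasing in x = 1/z

  # expand a sign-changing bracket around the initial guess
  lo <- 1 / (z0 * 4); hi <- 4 / z0
  glo <- g(lo); ghi <- g(hi)
  while (glo > 0 && lo > 1e-300) { lo <- lo / 16; glo <- g(lo) }
  while (ghi < 0 && hi < 1e300) { hi <- hi * 16; ghi <- g(hi) }
  if (glo > 0 || ghi < 0)
    abort_numerical("MLE score has no sign change in the search range")

  x0 <- 1 / z0
  x1 <- x0 * 1.001  # close-spaced pair: the first step is already Newton-like
  f0 <- g(x0); f1 <- g(x1)
  iter <- 0L
  xs <- numeric(0)
  repeat {
    if (iter >= 64L)
      abort_numerical(sprintf(
        "MLE secant did not converge in 64 iterations (last rate %.6g)", 1 / x1))
    step_ok <- is.finite(f0) && is.finite(f1) && f1 != f0
    x2 <- if (step_ok) x1 - f1 * (x1 - x0) / (f1 - f0) else NA_real_
    if (!step_ok || !is.finite(x2) || x2 < lo || x2 > hi)
      x2 <- (lo + hi) / 2  # guarded bisection fallback
    iter <- iter + 1L
    xs[iter] <- x2
    if (abs(x2 - x1) <= 1e-9 * abs(x1)) { x1 <- x2; break }
    f2 <- g(x2)
    if (f2 == 0) { x1 <- x2; break }
    if (f2 < 0) lo <- x2 else hi <- x2
    x0 <- x1; f0 <- f1
    x1 <- x2; f1 <- f2
  }
  # iterations-to-converge: first update already within tolerance of the
  # converged value (the remaining updates only detect the convergence)
  needed <- which(abs(xs - x1) <= 1e-9 * abs(x1))[1L]
  structure(m / x1, iterations = as.integer(needed))
}

#' Joint log-likelihood of a register pair under the mixture model
#'
#' Two sketches A and B are modelled as a mixture of three Poisson
#' components: elements unique to A (rate z_a per register), unique to B
#' (z_b), and shared (z_x). The joint CDF of a register pair is
#' F(a, b) = exp(-z_a phi(a) - z_b phi(b) - z_x phi(min(a, b))) and the
#' pmf is its two-dimensional difference. The likelihood is accumulated
#' over the tally of (value-in-A, value-in-B) pairs, an algebraic
#' regrouping of the per-register sum.
#'
#' @param lambda numeric length-3: cardinalities (lambda_a, lambda_b,
#'   lambda_x), all >= 0 (rates are lambda / m).
#' @param tally (q+2) x (q+2) matrix of register pair counts, as returned
#'   by [joint_register_tally()].
#' @param m register count; @param q suffix width.
#' @return log-likelihood; -Inf if any observed pair has non-positive
#'   probability at this point.
#' @export
joint_log_likelihood <- function(lambda, tally, m, q) {
  stopifnot(length(lambda) == 3L, all(lambda >= 0))
  z <- lambda / m
  phi <- c(2^-(0:q), 0)                      # phi[v + 1], v in 0..q+1
  ea <- exp(-z[1L] * phi)
  eb <- exp(-z[2L] * phi)
  phimin <- outer(phi, phi, pmax)  # phi is decreasing, so phi(min(a,b)) = max(phi(a), phi(b))
  n <- q + 2L
  # F over a, b in -1..q+1 (index v + 2); the -1 border row/col is 0
  Fm <- matrix(0, n + 1L, n + 1L)
  Fm[2:(n + 1), 2:(n + 1)] <- outer(ea, eb) * exp(-z[3L] * phimin)
  P <- Fm[2:(n + 1), 2:(n + 1)] - Fm[1:n, 2:(n + 1)] -
       Fm[2:(n + 1), 1:n] + Fm[1:n, 1:n]
  used <- tally > 0L
  if (any(P[used] <= 0)) return(-Inf)
  sum(tally[used] * log(P[used]))
}

#' Tally of paired register values
#'
#' Counts how often the register in A holds value v_a while its counterpart
#' in B holds v_b; the sufficient statistic for the joint MLE (equivalent to
#' the <, =, > comparison tallies).
#'
#' @param a,b compatible `hll_sketch` objects.
#' @return (q+2) x (q+2) integer matrix; entry \[i, j\] counts pairs with
#'   value i-1 in A and j-1 in B.
#' @export
joint_register_tally <- function(a, b) {
  check_compatible(a, b)
  cpp_joint_tally(a$registers, b$registers, a$q)
}

#' Joint maximum-likelihood estimate of A-only / B-only / shared cardinality
#'
#' Maximizes [joint_log_likelihood()] over (lambda_a, lambda_b, lambda_x)
#' >= 0 by cyclic coordinate ascent (golden-section line search per
#' coordinate), initialized from inclusion-exclusion of marginal MLE
#' estimates. Iteration stops when one full cycle moves every coordinate by
#' less than a relative 1e-6 (cap 100 cycles). Deterministic given the two
#' register arrays.
#'
#' @param a,b compatible `hll_sketch` objects.
#' @return list of class `jmle_estimate` with elements `lambda_a`,
#'   `lambda_b`, `lambda_x`, the implied `card_a`, `card_b`, `card_union`,
#'   `card_intersection`, `jaccard`, and `cycles`.
#' @export
estimate_jmle <- function(a, b) {
  check_compatible(a, b)
  m <- a$m; q <- a$q
  tally <- joint_register_tally(a, b)
  est_a <- as.numeric(estimate_mle(a))
  est_b <- as.numeric(estimate_mle(b))
  est_u <- as.numeric(estimate_mle(hll_union(a, b)))
  if (est_a == 0 && est_b == 0) {
    lam <- c(0, 0, 0)
    return(jmle_result(lam, m, 0L))
  }
  lx <- max(est_a + est_b - est_u, 0)
  lam <- c(max(est_a - lx, 0), max(est_b - lx, 0), lx)
  hi <- max(2 * est_u, 1)

  for (cycle in 1:100) {
    prev <- lam
    for (j in c(3L, 1L, 2L)) {
      f <- function(l) {
        lam[j] <- l
        joint_log_likelihood(lam, tally, m, q)
      }
      opt <- optimize(f, c(0, hi), maximum = TRUE,
                      tol = max(hi * 1e-10, 1e-12))
      # keep exact boundary if it is at least as good
      lam[j] <- if (f(0) >= opt$objective) 0 else opt$maximum
    }
    delta <- abs(lam - prev) / pmax(lam, prev, 1)
    if (max(delta) < 1e-6) return(jmle_result(lam, m, cycle))
  }
  abort_numerical(sprintf(
    "joint MLE did not converge in 100 cycles (last iterate %.6g/%.6g/%.6g)",
    lam[1], lam[2], lam[3]))
}

jmle_result <- function(lam, m, cycles) {
  u <- sum(lam)
  structure(list(
    lambda_a = lam[1L], lambda_b = lam[2L], lambda_x = lam[3L],
    card_a = lam[1L] + lam[3L], card_b = lam[2L] + lam[3L],
    card_union = u, card_intersection = lam[3L],
    jaccard = if (u > 0) lam[3L] / u else 0,
    cycles = cycles), class = "jmle_estimate")
}

#' @export
print.jmle_estimate <- function(x, ...) {
  cat(sprintf("<jmle_estimate> |A|=%.4g |B|=%.4g |A:B|=%.4g J=%.6g (%d cycles)\n",
              x$card_a, x$card_b, x$card_intersection, x$jaccard, x$cycles))
  invisible(x)
}

#' Intersection cardinality by inclusion-exclusion
#'
#' est(A) + est(B) - est(A union B), floored at 0; the union sketch is the
#' exact element-wise register maximum, so for identical sketches the
#' result collapses to est(A) exactly.
#'
#' @param a,b compatible `hll_sketch` objects.
#' @param estimator "original" or "mle".
#' @return estimated intersection cardinality (>= 0).
#' @export
intersection_inclusion_exclusion <- function(a, b, estimator = c("mle", "original")) {
  estimator <- match.arg(estimator)
  est <- switch(estimator, mle = function(s) as.numeric(estimate_mle(s)),
                original = estimate_original)
  max(est(a) + est(b) - est(hll_union(a, b)), 0)
}
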