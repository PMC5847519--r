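# Shared fixtures: all synthetic, generated in code.

noiseless_curve <- function(A = 100, f = 0.6, t2s = 5, t2l = 30, ric = 0,
                            schedule = make_default_schedule()) {
  data.frame(te_ms = schedule$te_ms, run = schedule$run,
             signal = biexp_signal(schedule$te_ms, A, f, t2s, t2l, ric))
}

noiseless_tube <- function(m0 = 150, t2star = 12, ric = 0,
                           schedule = make_default_schedule()) {
  data.frame(te_ms = schedule$te_ms, run = schedule$run,
             signal = monoexp_signal(schedule$te_ms, m0, t2star, ric))
}

# Independent Steel-Dwass oracle for one pair of small samples:
# the Mann-Whitney U by direct pair counting, the null variance of the
# rank sum by exhaustive enumeration of all subsets of the pooled ranks.
brute_force_pair_z <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
  u <- 0
  for (a in x1) for (b in x2) u <- u + (a > b) + 0.5 * (a == b)
  w <- u + n1 * (n1 + 1) / 2
  r <- rank(c(x1, x2))
  subsets <- utils::combn(N, n1)
  wsums <- apply(subsets, 2, function(idx) sum(r[idx]))
  e <- mean(wsums)
  v <- mean((wsums - e)^2)  # exact null variance over all assignments
  d <- w - e
  sign(d) * max(abs(d) - 0.5, 0) / sqrt(v)
}
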