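# Independent oracles used across the suite.

# AUC by brute-force pair counting (ties count one half)
auc_pair_count <- function(cases, controls) {
  wins <- 0
  for (x in cases) for (y in controls)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(cases) * length(controls))
}

# partial binormal AUC by a dense midpoint Riemann sum over the FPR scale:
# theta = int Phi(A + B * qnorm(t)) dt over t in (lo, hi)
auc_riemann <- function(A, B, lo, hi, points = 1e6) {
  t <- seq(lo, hi, length.out = points + 1)
  mid <- (t[-1] + t[-length(t)]) / 2
  sum(pnorm(A + B * qnorm(mid))) * (hi - lo) / points
}

# Obuchowski-McClish constants written out independently (full FPR range)
om_constants_oracle <- function(A, B) {
  E1 <- exp(-A^2 / (2 + 2 * B^2))
  list(f = E1 / sqrt(2 * pi * (1 + B^2)),
       g = -A * B * E1 / sqrt(2 * pi * (1 + B^2)^3))
}
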