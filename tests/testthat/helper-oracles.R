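# Independent closed-form oracles used across the suite.  These are written
# against the analytic solutions of the underlying boundary-value problems,
# not against the package's numerical code paths.

oracle_erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
oracle_erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

# semi-infinite medium, constant surface concentration c0, zero start:
# c(x, t) = c0 * erfc(x / (2 sqrt(D t)))
oracle_semiinf_profile <- function(x, t, D, c0) {
  c0 * oracle_erfc(x / (2 * sqrt(D * t)))
}

# finite slab 0..L, c(0)=c0, no-flux at L, c(x,0)=0: eigenfunction series for
# the wall concentration ratio c(L, t) / c0
oracle_slab_wall_ratio <- function(t, D, L, nterms = 400) {
  n <- 0:nterms
  1 - (4 / pi) * sum((-1)^n / (2 * n + 1) *
                       exp(-D * (2 * n + 1)^2 * pi^2 * t / (4 * L^2)))
}

# breakthrough time: root of the series wall ratio on the threshold
oracle_breakthrough <- function(D, L, ratio) {
  f <- function(t) oracle_slab_wall_ratio(t, D, L) - ratio
  uniroot(f, c(1e-3, 1e10), tol = 1e-8)$root
}

# left-hand side of the similarity root equation of the immobilization
# Stefan problem, evaluated directly
oracle_stefan_lhs <- function(beta) {
  sqrt(pi) * beta * exp(beta^2) * oracle_erf(beta)
}

# reference constants of the test system, duplicated numerically so a typo
# in the package constants cannot silently propagate
REF <- list(D_volume = 8.901e-11, Di = 1.6761e-10, alpha = 0.027,
            c0 = 159.9, c_threshold = 24.23)
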