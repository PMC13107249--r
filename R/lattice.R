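# D3Q19 lattice definition and the reference (R-level) collision operators.
# The compiled kernel in src/ uses the same velocity ordering; tests verify
# the two paths agree.

#' The D3Q19 lattice
#'
#' Builds the 19-velocity set (rest, 6 axis, 12 edge-diagonal), its weights,
#' the opposite-direction map, and the orthogonal moment matrix used by the
#' MRT collision operator. Moment rows are the standard polynomial basis:
#' density, energy, energy square, momentum and heat-flux pairs per axis,
#' the five second-order (shear) moments with their fourth-order partners,
#' and the three third-order antisymmetric moments.
#'
#' @return a [LatticeD3Q19-class].
#' @export
latticeD3Q19 <- function() {
  cs <- rbind(
    c(0, 0, 0),
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
    c(1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0),
    c(1, 0, 1), c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1),
    c(0, 1, 1), c(0, -1, -1), c(0, 1, -1), c(0, -1, 1)
  )
  w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  opp <- integer(19)
  for (i in 1:19) opp[i] <- which(colSums(abs(t(cs) + cs[i, ])) == 0)
  cx <- cs[, 1]; cy <- cs[, 2]; cz <- cs[, 3]
  c2 <- cx^2 + cy^2 + cz^2
  M <- rbind(
    rep(1, 19),
    19 * c2 - 30,
    (21 * c2^2 - 53 * c2 + 24) / 2,
    cx, (5 * c2 - 9) * cx,
    cy, (5 * c2 - 9) * cy,
    cz, (5 * c2 - 9) * cz,
    3 * cx^2 - c2, (3 * c2 - 5) * (3 * cx^2 - c2),
    cy^2 - cz^2, (3 * c2 - 5) * (cy^2 - cz^2),
    cx * cy, cy * cz, cx * cz,
    (cy^2 - cz^2) * cx, (cz^2 - cx^2) * cy, (cx^2 - cy^2) * cz
  )
  Minv <- t(M) %*% diag(1 / rowSums(M^2))
  new("LatticeD3Q19", c = cs, w = w, opp = opp, csSq = 1 / 3, M = M, Minv = Minv)
}

# moment-row categories (1-based indices into the basis above)
.mrt_conserved <- c(1L, 4L, 6L, 8L)
.mrt_shear <- c(10L, 12L, 14L, 15L, 16L)

#' Default MRT relaxation rates
#'
#' Conserved moments (density, momentum) get rate 0 (their relaxation is
#' irrelevant: they are exact collision invariants); the five shear-stress
#' moments get `1/tau` so the shear viscosity matches the SRT value; all
#' remaining (kinetic) moments get `others`.
#'
#' @param tau SRT relaxation time the shear viscosity is matched to.
#' @param others rate for the non-hydrodynamic moments.
#' @return length-19 rate vector.
#' @export
mrtRates <- function(tau, others = 1.2) {
  s <- rep(others, 19)
  s[.mrt_conserved] <- 0
  s[.mrt_shear] <- 1 / tau
  s
}

#' Discrete Maxwellian equilibrium
#'
#' Second-order equilibrium `f_i^eq = w_i rho [1 + (c.u)/cs2 +
#' (c.u)^2/(2 cs2^2) - u^2/(2 cs2)]`.
#'
#' @param rho density, length n.
#' @param u velocity, n x 3 (lattice units; warn above 0.1, the expansion
#'   degrades well below the 0.3 stability bound).
#' @param lattice a [LatticeD3Q19-class].
#' @return n x 19 matrix of equilibrium populations.
#' @export
equilibriumD3Q19 <- function(rho, u, lattice = latticeD3Q19()) {
  u <- matrix(u, ncol = 3)
  sp <- max(sqrt(rowSums(u^2)))
  if (sp > 0.3) stop("|u| = ", signif(sp, 3), " exceeds the 0.3 lattice-unit bound")
  if (sp > 0.1) warning("|u| above 0.1 lattice units; equilibrium accuracy degrades")
  cu <- u %*% t(lattice@c)                     # n x 19
  u2 <- rowSums(u^2)                           # recycles down columns
  poly <- 1 + 3 * cu + 4.5 * cu^2 - 1.5 * u2
  t(lattice@w * t(rho * poly))
}

#' Macroscopic moments of a distribution set
#'
#' `rho = sum_i f_i`, `u = sum_i f_i c_i / rho`, `p = cs2 (rho - rho0)`
#' (lattice units).
#'
#' @param f n x 19 populations.
#' @param lattice a [LatticeD3Q19-class].
#' @param rho0 reference density.
#' @return list with `rho` (n), `u` (n x 3), `p` (n).
#' @export
macroscopics <- function(f, lattice = latticeD3Q19(), rho0 = 1) {
  f <- matrix(f, ncol = 19)
  rho <- rowSums(f)
  if (any(rho <= 0)) stop("non-positive density: the simulation is unstable")
  u <- (f %*% lattice@c) / rho
  list(rho = rho, u = u, p = lattice@csSq * (rho - rho0))
}

#' Single-relaxation-time (BGK) collision
#'
#' `f' = f - (f - f^eq)/tau`, with the equilibrium evaluated at the
#' distribution's own density and velocity; mass and momentum are conserved
#' exactly and `f^eq` is a fixed point.
#'
#' @param f n x 19 populations.
#' @param tau relaxation time, `> 0.5` for stability.
#' @param lattice a [LatticeD3Q19-class].
#' @return collided n x 19 populations.
#' @export
collideSRT <- function(f, tau, lattice = latticeD3Q19()) {
  if (tau <= 0.5) stop("tau must exceed 0.5")
  f <- matrix(f, ncol = 19)
  mac <- macroscopics(f, lattice)
  feq <- equilibriumD3Q19(mac$rho, mac$u, lattice)
  f - (f - feq) / tau
}

#' Multi-relaxation-time (MRT) collision
#'
#' Moments `m = M f` are relaxed toward the moments of the local equilibrium
#' with per-moment rates: `f' = f - M^-1 S M (f - f^eq)`. With every rate
#' equal to `1/tau` this reduces exactly to [collideSRT()]; distinct rates
#' for the non-hydrodynamic moments buy stability at low viscosity.
#'
#' @param f n x 19 populations.
#' @param rates length-19 rate vector (see [mrtRates()]); non-conserved
#'   rates must lie in (0, 2), conserved rates may be 0.
#' @param lattice a [LatticeD3Q19-class].
#' @return collided n x 19 populations.
#' @export
collideMRT <- function(f, rates, lattice = latticeD3Q19()) {
  stopifnot(length(rates) == 19)
  free <- setdiff(seq_len(19), .mrt_conserved)
  if (any(rates[free] <= 0) || any(rates[free] >= 2))
    stop("non-conserved MRT rates must lie in (0, 2)")
  if (any(rates[.mrt_conserved] < 0) || any(rates[.mrt_conserved] >= 2))
    stop("conserved MRT rates must lie in [0, 2)")
  f <- matrix(f, ncol = 19)
  mac <- macroscopics(f, lattice)
  feq <- equilibriumD3Q19(mac$rho, mac$u, lattice)
  A <- lattice@Minv %*% (rates * lattice@M)
  f - (f - feq) %*% t(A)
}
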