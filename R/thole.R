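## Induced-dipole model with Thole damping. Each atom is an isotropically
## polarizable point; the induced dipoles minimize
##
##   E(mu) = -sum_i mu_i . E_i  -  1/2 sum_{i != j} mu_i . T_ij . mu_j
##         + sum_i |mu_i|^2 / (2 alpha_i)
##
## where T_ij is the dipole-dipole interaction tensor attenuated at short
## range by cubic-exponential Thole damping in the reduced distance
## u = r / (alpha_i alpha_j)^(1/6):
##
##   T_ij = lambda5(u) 3 r r^T / r^5  -  lambda3(u) I / r^3
##   lambda3 = 1 - exp(-a u^3),  lambda5 = 1 - (1 + a u^3) exp(-a u^3)
##
## Stationarity gives the 3N relay system (alpha^-1 - T) mu = E. The MM
## charge fields themselves are undamped; damping applies only to the
## intramolecular dipole-dipole coupling.

#' Assemble a Thole polarizability system
#'
#' @param alpha per-atom isotropic polarizabilities, Bohr^3 (> 0).
#' @param positions n x 3 nuclear positions, Bohr.
#' @param a_thole dimensionless Thole damping factor (> 0).
#' @return An object of class `mlmm_thole_system`.
#' @export
thole_system <- function(alpha, positions, a_thole) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- length(alpha)
  stopifnot(n >= 1, nrow(positions) == n)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be positive and finite", call. = FALSE)
  if (!is.finite(a_thole) || a_thole <= 0)
    stop("a_thole must be > 0", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), positions = unname(positions),
                 a_thole = as.numeric(a_thole)),
            class = "mlmm_thole_system")
}

#' Coulomb fields of MM point charges at the nuclei
#'
#' Undamped fields \eqn{E_i = \sum_m q_m (R_i - r_m)/|R_i - r_m|^3} in atomic
#' units; the inputs are in the package's I/O units (Angstrom).
#'
#' @param mol an [molecule()].
#' @param mm an [mm_charges()] mesh (may be empty).
#' @return n x 3 matrix of fields, Hartree/(e Bohr).
#' @export
mm_fields <- function(mol, mm) {
  n <- n_atoms(mol)
  E <- matrix(0, n, 3)
  if (n_charges(mm) == 0) return(E)
  at <- to_bohr(mol$xyz)
  pc <- to_bohr(mm$positions)
  for (i in seq_len(n)) {
    dv <- sweep(pc, 2, at[i, ], "-")        # vectors nucleus -> charge
    d <- sqrt(rowSums(dv^2))
    if (any(d < MIN_SITE_DIST_BOHR))
      stop(sprintf("MM charge coincides with nucleus %d", i), call. = FALSE)
    E[i, ] <- -colSums(mm$charges * dv / d^3)  # field points away from +q
  }
  E
}

## damping factors for a vector of x = a*u^3 values; series branch avoids
## catastrophic cancellation of 1 - (1+x)exp(-x) at small x
.thole_lambdas <- function(x) {
  l3 <- -expm1(-x)
  l5 <- 1 - (1 + x) * exp(-x)
  small <- x < 1e-3
  if (any(small)) {
    xs <- x[small]
    l5[small] <- xs^2 / 2 - xs^3 / 3 + xs^4 / 8 - xs^5 / 30
  }
  list(l3 = l3, l5 = l5)
}

#' Thole-damped dipole-dipole interaction tensor
#'
#' The 3 x 3 coupling block between atoms `i` and `j` of the relay system.
#' Symmetric in `(i, j)`; reduces to the bare tensor at large reduced
#' distance and stays finite as the atoms coalesce.
#'
#' @param sys an [thole_system()].
#' @param i,j distinct atom indices.
#' @return 3 x 3 numeric matrix, Bohr^-3.
#' @export
damped_dipole_tensor <- function(sys, i, j) {
  if (i == j) stop("dipole tensor needs i != j", call. = FALSE)
  rvec <- sys$positions[j, ] - sys$positions[i, ]
  r <- sqrt(sum(rvec^2))
  u <- r / (sys$alpha[i] * sys$alpha[j])^(1 / 6)
  lam <- .thole_lambdas(sys$a_thole * u^3)
  if (r < 1e-12)  # coalescence limit: lambda3/r^3 -> a/sqrt(ai aj), lambda5 term -> 0
    return(-sys$a_thole / sqrt(sys$alpha[i] * sys$alpha[j]) * diag(3))
  lam$l5 * 3 * tcrossprod(rvec) / r^5 - lam$l3 * diag(3) / r^3
}

## full 3n x 3n relay matrix alpha^-1 - T; errors with the offending pair on
## loss of positive definiteness (the polarization catastrophe)
.thole_relay <- function(sys) {
  n <- length(sys$alpha)
  A <- diag(rep(1 / sys$alpha, each = 3))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      Tij <- damped_dipole_tensor(sys, i, j)
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      A[ri, rj] <- A[ri, rj] - Tij
      A[rj, ri] <- A[rj, ri] - t(Tij)
    }
  }
  A
}

.thole_chol <- function(sys) {
  A <- .thole_relay(sys)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    # name the closest pair in reduced distance: the usual culprit
    n <- length(sys$alpha)
    worst <- c(1L, 2L); umin <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- sqrt(sum((sys$positions[i, ] - sys$positions[j, ])^2))
      u <- r / (sys$alpha[i] * sys$alpha[j])^(1 / 6)
      if (u < umin) { umin <- u; worst <- c(i, j) }
    }
    stop(sprintf(paste0("polarization catastrophe: relay matrix is not ",
                        "positive definite (closest reduced pair %d-%d, ",
                        "u = %.3f); increase a_thole or fix the geometry"),
                 worst[1], worst[2], umin), call. = FALSE)
  }
  ch
}

#' Solve for the induced dipoles
#'
#' Direct dense solve of the 3N relay system
#' \eqn{(\alpha^{-1} - T)\mu = E}. Fails with a physics-level error when the
#' relay matrix loses positive definiteness (polarization catastrophe).
#'
#' @param sys an [thole_system()].
#' @param fields n x 3 matrix of external fields at the nuclei,
#'   Hartree/(e Bohr).
#' @return A list of class `mlmm_induced_dipoles` with `mu` (n x 3, e Bohr)
#'   and `fields` (the input fields).
#' @export
solve_dipoles <- function(sys, fields) {
  n <- length(sys$alpha)
  fields <- matrix(as.numeric(fields), ncol = 3)
  stopifnot(nrow(fields) == n)
  ch <- .thole_chol(sys)
  mu <- matrix(backsolve(ch, backsolve(ch, as.numeric(t(fields)),
                                       transpose = TRUE)),
               n, 3, byrow = TRUE)
  structure(list(mu = mu, fields = fields), class = "mlmm_induced_dipoles")
}

#' Polarization energy cost
#'
#' \eqn{E^{pol} = \sum_i |\mu_i|^2 / (2\alpha_i)}: the energy required to
#' create the induced dipoles; always non-negative.
#'
#' @param sys an [thole_system()].
#' @param dipoles an `mlmm_induced_dipoles` (or an n x 3 matrix of dipoles).
#' @return Energy, Hartree.
#' @export
polarization_cost <- function(sys, dipoles) {
  mu <- if (inherits(dipoles, "mlmm_induced_dipoles")) dipoles$mu else
    matrix(as.numeric(dipoles), ncol = 3)
  sum(rowSums(mu^2) / (2 * sys$alpha))
}

#' Potential of the induced dipoles at external points
#'
#' \eqn{V^{ind}(r) = \sum_i \mu_i \cdot (r - R_i)/|r - R_i|^3} (point-dipole
#' potential, undamped: damping applies only intramolecularly).
#'
#' @param sys an [thole_system()].
#' @param dipoles an `mlmm_induced_dipoles` or n x 3 dipole matrix, e Bohr.
#' @param points m x 3 matrix of evaluation points, Bohr.
#' @return Numeric vector of potentials, Hartree/e.
#' @export
induced_potential <- function(sys, dipoles, points) {
  mu <- if (inherits(dipoles, "mlmm_induced_dipoles")) dipoles$mu else
    matrix(as.numeric(dipoles), ncol = 3)
  points <- matrix(as.numeric(points), ncol = 3)
  v <- numeric(nrow(points))
  for (i in seq_len(nrow(mu))) {
    dv <- sweep(points, 2, sys$positions[i, ], "-")
    d <- sqrt(rowSums(dv^2))
    if (any(d < MIN_SITE_DIST_BOHR))
      stop(sprintf("evaluation point coincides with atom %d", i), call. = FALSE)
    v <- v + drop(dv %*% mu[i, ]) / d^3
  }
  v
}

#' Molecular dipolar polarizability tensor
#'
#' The symmetric 3 x 3 tensor mapping a uniform external field to the total
#' induced molecular dipole, obtained by solving the relay system for the
#' three Cartesian unit fields and summing dipoles. Exactly symmetrized on
#' output (the raw asymmetry is at solver-roundoff level).
#'
#' @param sys an [thole_system()].
#' @return 3 x 3 numeric matrix, Bohr^3.
#' @export
molecular_polarizability <- function(sys) {
  n <- length(sys$alpha)
  ch <- .thole_chol(sys)
  a <- matrix(0, 3, 3)
  for (k in 1:3) {
    E <- matrix(0, n, 3); E[, k] <- 1
    mu <- matrix(backsolve(ch, backsolve(ch, as.numeric(t(E)),
                                         transpose = TRUE)),
                 n, 3, byrow = TRUE)
    a[, k] <- colSums(mu)
  }
  (a + t(a)) / 2
}

#' Map atomic volumes to polarizabilities
#'
#' \eqn{\alpha_i = k_{Z(i)} V_i}: atomic polarizability proportional to the
#' MBIS atomic volume, with one free-atom ratio per element.
#'
#' @param volumes per-atom volumes, Bohr^3.
#' @param elements per-atom element symbols.
#' @param k_z named numeric vector of polarizability/volume ratios (Bohr^3
#'   per Bohr^3, i.e. dimensionless), one entry per element present.
#' @return Per-atom polarizabilities, Bohr^3.
#' @export
volumes_to_alphas <- function(volumes, elements, k_z) {
  miss <- setdiff(unique(elements), names(k_z))
  if (length(miss))
    stop("k_z table is missing element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(k_z[unique(elements)])) || any(k_z[unique(elements)] <= 0))
    stop("k_z must be positive for every element present", call. = FALSE)
  unname(k_z[elements] * volumes)
}
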