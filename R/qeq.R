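## Charge equilibration (electronegativity equalization) with Gaussian atomic
## charge densities. Each atom i carries a spherical normal distribution of
## total charge q_i and standard deviation sigma_i,
##
##   rho_i(r) = q_i (2 pi sigma_i^2)^(-3/2) exp(-|r - R_i|^2 / (2 sigma_i^2)),
##
## and the charges minimize
##
##   E(q) = sum_i chi_i q_i + 1/2 sum_i J_i q_i^2
##        + sum_{i<j} E_ij(R_ij) q_i q_j
##
## subject to sum_i q_i = q_tot. J is the Gaussian self-interaction integral
## (the R -> 0 coalescence limit of the pair term, so diagonal and
## off-diagonal entries come from one consistent convention).

#' Chemical hardness of a Gaussian charge distribution
#'
#' Self-interaction integral of a unit normal charge density with standard
#' deviation `sigma`: \eqn{J(\sigma) = 1/(\sigma\sqrt{\pi})}. Strictly
#' decreasing and scaling as \eqn{1/\sigma}; equals the coalescence limit of
#' [qeq_pair_interaction()].
#'
#' @param sigma Gaussian width(s), Bohr (> 0).
#' @return Hardness in Hartree/e^2, vectorized.
#' @export
qeq_hardness <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("hardness requires sigma > 0", call. = FALSE)
  1 / (sigma * sqrt(pi))
}

#' Coulomb interaction of two Gaussian charge distributions
#'
#' Per-unit-charge interaction energy of two normal densities with widths
#' `sigma_i`, `sigma_j` separated by `R`:
#' \deqn{E_{ij}(R) = \mathrm{erf}\!\left(R / \sqrt{2(\sigma_i^2+\sigma_j^2)}\right)/R}
#' Finite at `R = 0` (where it equals
#' \eqn{\sqrt{2/\pi}/\sqrt{\sigma_i^2+\sigma_j^2}}), symmetric in the widths,
#' and tending to `1/R` at long range.
#'
#' @param sigma_i,sigma_j Gaussian widths, Bohr (> 0).
#' @param R separation(s), Bohr (>= 0).
#' @return Interaction in Hartree/e^2, vectorized over `R`.
#' @export
qeq_pair_interaction <- function(sigma_i, sigma_j, R) {
  if (any(!is.finite(c(sigma_i, sigma_j))) || any(c(sigma_i, sigma_j) <= 0))
    stop("pair interaction requires sigma > 0", call. = FALSE)
  if (any(!is.finite(R)) || any(R < 0))
    stop("pair interaction requires R >= 0", call. = FALSE)
  g <- rep_len(sqrt(2 * (sigma_i^2 + sigma_j^2)), length(R))
  u <- R / g
  out <- numeric(length(R))
  small <- u < 1e-4
  # erf(u)/R with erf(u) = 2*pnorm(u*sqrt(2)) - 1; series near coalescence
  out[!small] <- (2 * stats::pnorm(sqrt(2) * u[!small]) - 1) / R[!small]
  out[small] <- 2 / (sqrt(pi) * g[small]) *
    (1 - u[small]^2 / 3 + u[small]^4 / 10)
  out
}

#' Assemble a charge-equilibration system
#'
#' @param chi per-atom electronegativities, Hartree/e.
#' @param sigma per-atom Gaussian widths, Bohr (> 0).
#' @param positions n x 3 matrix of nuclear positions, Bohr.
#' @param q_tot total molecular charge, e.
#' @return An object of class `mlmm_qeq_system`.
#' @export
qeq_system <- function(chi, sigma, positions, q_tot = 0) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- length(chi)
  stopifnot(n >= 1, length(sigma) == n, nrow(positions) == n)
  if (any(!is.finite(chi)) || any(!is.finite(sigma)) || any(sigma <= 0) ||
      !all(is.finite(positions)) || !is.finite(q_tot))
    stop("invalid QEq system", call. = FALSE)
  structure(list(chi = as.numeric(chi), sigma = as.numeric(sigma),
                 positions = unname(positions), q_tot = as.numeric(q_tot)),
            class = "mlmm_qeq_system")
}

## hardness/interaction matrix A (n x n) of a QEq system
.qeq_matrix <- function(sys) {
  n <- length(sys$chi)
  A <- matrix(0, n, n)
  diag(A) <- qeq_hardness(sys$sigma)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      R <- sqrt(colSums((t(sys$positions[j, , drop = FALSE]) -
                           sys$positions[i, ])^2))
      A[i, j] <- A[j, i] <- qeq_pair_interaction(sys$sigma[i], sys$sigma[j], R)
    }
  }
  A
}

#' Solve the charge-equilibration system
#'
#' Minimizes the QEq energy under the total-charge constraint by a direct
#' dense solve of the bordered (n+1) x (n+1) KKT system
#' \eqn{[A\ \mathbf{1}; \mathbf{1}^T\ 0]\,[q;\lambda] = [-\chi; q_{tot}]}.
#'
#' @param sys an [qeq_system()].
#' @param cond_limit condition-number limit beyond which the solve aborts.
#' @return A list of class `mlmm_qeq_solution` with `charges` (e),
#'   `lagrange_multiplier` (Hartree/e) and `energy` (Hartree, the minimized
#'   QEq objective).
#' @export
solve_qeq <- function(sys, cond_limit = 1e12) {
  n <- length(sys$chi)
  A <- .qeq_matrix(sys)
  M <- rbind(cbind(A, 1), c(rep(1, n), 0))
  kap <- kappa(M, exact = FALSE)
  if (!is.finite(kap) || kap > cond_limit)
    stop(sprintf(paste0("QEq KKT system is ill-conditioned ",
                        "(condition number %.3g > %.3g); check widths and ",
                        "geometry"), kap, cond_limit), call. = FALSE)
  x <- solve(M, c(-sys$chi, sys$q_tot))
  q <- x[seq_len(n)]
  energy <- sum(sys$chi * q) + 0.5 * drop(q %*% A %*% q)
  structure(list(charges = q, lagrange_multiplier = x[n + 1], energy = energy),
            class = "mlmm_qeq_solution")
}

#' @export
print.mlmm_qeq_solution <- function(x, ...) {
  cat(sprintf("<mlmm_qeq_solution> %d charges, sum %+.6f e, E = %.8f Ha\n",
              length(x$charges), sum(x$charges), x$energy))
  invisible(x)
}
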