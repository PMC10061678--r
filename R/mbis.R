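## Static (in vacuo) electrostatic model.
##
## Each atom carries a point-like "core" charge q_core (nucleus + core
## electrons, so q_core = Z - N_core >= 0) and a Slater valence shell with
## N_val electrons, density
##
##   rho_val(r) = N_val / (8 pi s^3) * exp(-r / s)
##
## carrying charge q_val = -N_val. The electrostatic potential of this
## core+valence distribution is analytic; far from the atom it tends to
## (q_core + q_val) / r.

MIN_SITE_DIST_BOHR <- 1e-6  # evaluation points closer than this to a nucleus
                            # are a hard error, not a clamp

#' Potential of a Slater core+valence atomic density
#'
#' Analytic electrostatic potential, at distance `r` from the nucleus, of a
#' point core charge `q_core` plus a Slater valence shell of width `s`
#' carrying charge `q_val` (so the valence electron count is `-q_val`):
#' \deqn{V(r) = q_{core}/r + q_{val}\left[\frac{1}{r} -
#'   e^{-r/s}\left(\frac{1}{r} + \frac{1}{2s}\right)\right]}
#' Charges carry sign: electronic parts are negative, and a neutral atom has
#' `q_core + q_val = 0`.
#'
#' @param q_core core charge, e.
#' @param q_val valence charge, e (`-N_val`).
#' @param s valence Slater width, Bohr (> 0).
#' @param r distance(s) from the nucleus, Bohr (> 0).
#' @return Potential in Hartree/e, vectorized over `r`.
#' @export
slater_potential <- function(q_core, q_val, s, r) {
  stopifnot(length(q_core) == 1, length(q_val) == 1, length(s) == 1)
  if (!is.finite(s) || s <= 0) stop("Slater width s must be > 0", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("slater_potential requires r > 0", call. = FALSE)
  q_core / r + q_val * (1 / r - exp(-r / s) * (1 / r + 1 / (2 * s)))
}

#' Per-atom static density parameters for a molecule
#'
#' Bundles aligned vectors of core charge, valence charge and Slater width,
#' one entry per atom of `mol`. The summed charges must equal the molecular
#' total charge (the model represents the whole density).
#'
#' @param mol an [molecule()].
#' @param q_core,q_val numeric per-atom charges, e.
#' @param s numeric per-atom Slater valence widths, Bohr (> 0).
#' @return An object of class `mlmm_static_model`.
#' @export
static_density_model <- function(mol, q_core, q_val, s) {
  n <- n_atoms(mol)
  stopifnot(length(q_core) == n, length(q_val) == n, length(s) == n)
  if (any(!is.finite(c(q_core, q_val, s))) || any(s <= 0))
    stop("invalid density parameters (need finite values, s > 0)", call. = FALSE)
  z <- atomic_number(mol$elements)
  if (any(q_core < -1e-8 | q_core > z + 1e-8))
    stop("q_core outside [0, Z] for some atom", call. = FALSE)
  tot <- sum(q_core + q_val)
  if (abs(tot - mol$total_charge) > 1e-8)
    stop(sprintf("density charges sum to %.10f but molecule charge is %d",
                 tot, mol$total_charge), call. = FALSE)
  structure(list(q_core = as.numeric(q_core), q_val = as.numeric(q_val),
                 s = as.numeric(s)),
            class = "mlmm_static_model")
}

## distances (Bohr) from each atom of mol to each evaluation point (Angstrom
## in, rows = points, cols = atoms); errors if any point sits on a nucleus
.site_dist_bohr <- function(mol, points_ang) {
  pts <- to_bohr(matrix(as.numeric(points_ang), ncol = 3))
  at <- to_bohr(mol$xyz)
  d2 <- outer(rowSums(pts^2), rep(1, nrow(at))) +
        outer(rep(1, nrow(pts)), rowSums(at^2)) -
        2 * pts %*% t(at)
  d <- sqrt(pmax(d2, 0))
  if (any(d < MIN_SITE_DIST_BOHR)) {
    ij <- which(d < MIN_SITE_DIST_BOHR, arr.ind = TRUE)[1, ]
    stop(sprintf("evaluation point %d coincides with nucleus %d (d = %.3g Bohr)",
                 ij[1], ij[2], d[ij[1], ij[2]]), call. = FALSE)
  }
  d
}

#' Static electrostatic potential of the nonpolarized molecule
#'
#' Superposition of [slater_potential()] over all atoms, evaluated at a set of
#' Cartesian points.
#'
#' @param model an [static_density_model()].
#' @param mol the [molecule()] the model is aligned with.
#' @param points numeric m x 3 matrix of evaluation points, Angstrom.
#' @return Numeric vector of potentials, Hartree/e.
#' @export
static_potential <- function(model, mol, points) {
  d <- .site_dist_bohr(mol, points)  # m x n
  v <- numeric(nrow(d))
  for (i in seq_len(n_atoms(mol)))
    v <- v + slater_potential(model$q_core[i], model$q_val[i], model$s[i],
                              d[, i])
  v
}

#' Static embedding energy
#'
#' Interaction energy between the nonpolarized molecular density and an MM
#' point-charge mesh: \eqn{\sum_i q_i V^{static}(r_i)}. An empty mesh gives
#' exactly zero.
#'
#' @param model an [static_density_model()].
#' @param mol the matching [molecule()].
#' @param mm an [mm_charges()] mesh.
#' @return Energy in Hartree.
#' @export
static_embedding_energy <- function(model, mol, mm) {
  if (n_charges(mm) == 0) return(0)
  sum(mm$charges * static_potential(model, mol, mm$positions))
}

#' MBIS atomic volume
#'
#' Third radial moment of the Slater valence density,
#' \eqn{V = \int r^3 \rho_{val}(r)\, d^3r = 60\, N_{val}\, s^3}
#' (with the \eqn{4\pi r^2} radial measure). Scales cubically in `s` and
#' linearly in the valence electron count; used to map densities to atomic
#' polarizabilities.
#'
#' @param q_val valence charge(s), e (`N_val = -q_val` must be >= 0).
#' @param s Slater width(s), Bohr (> 0).
#' @return Volume(s), Bohr^3. Vectorized.
#' @export
atomic_volume <- function(q_val, s) {
  n_val <- -as.numeric(q_val)
  if (any(!is.finite(n_val)) || any(n_val < -1e-10))
    stop("atomic_volume requires N_val = -q_val >= 0", call. = FALSE)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("atomic_volume requires s > 0", call. = FALSE)
  60 * pmax(n_val, 0) * s^3
}
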