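## Synthetic fixtures and independent numerical oracles.
##
## The generator emulates the statistics of the reference training data (per-
## atom densities from a DFT partitioning, per-molecule polarizability
## tensors) from a known ground-truth parameter set, so the full training
## workflow can be exercised and checked by parameter recovery without any
## external data. Electronegativities and valence widths vary smoothly with
## a soft coordination count so the descriptor/GPR layer has genuine signal
## to learn, not just per-element constants.

#' Shell-theorem potential of a spherical density by adaptive quadrature
#'
#' Normative numerical oracle for every analytic radial potential in the
#' package: for a spherical charge density `rho(r)` (charge per Bohr^3),
#' \deqn{V(r) = \frac{4\pi}{r}\int_0^r x^2\rho(x)dx + 4\pi\int_r^\infty x\rho(x)dx.}
#' Implemented with [stats::integrate()] at tight tolerances; independent of
#' the closed forms it is used to check.
#'
#' @param rho vectorized radial density function, charge/Bohr^3.
#' @param r evaluation distance, Bohr (> 0).
#' @param upper upper integration limit standing in for infinity, Bohr.
#' @return Potential, Hartree/e.
#' @export
quadrature_potential <- function(rho, r, upper = Inf) {
  stopifnot(r > 0)
  inner <- stats::integrate(function(x) x^2 * rho(x), 0, r,
                            rel.tol = 1e-12, abs.tol = 1e-14)
  outer_ <- stats::integrate(function(x) x * rho(x), r, upper,
                             rel.tol = 1e-12, abs.tol = 1e-14)
  if (inner$message != "OK" || outer_$message != "OK")
    stop("quadrature did not converge", call. = FALSE)
  4 * pi * (inner$value / r + outer_$value)
}

#' Slater core+valence potential by quadrature
#'
#' Point core plus numerically integrated Slater valence shell; oracle for
#' [slater_potential()].
#'
#' @inheritParams slater_potential
#' @return Potential, Hartree/e (scalar `r`).
#' @export
oracle_slater_potential <- function(q_core, q_val, s, r) {
  rho <- function(x) q_val / (8 * pi * s^3) * exp(-x / s)
  q_core / r + quadrature_potential(rho, r)
}

#' Slater valence volume by quadrature
#'
#' \eqn{\int r^3 \rho_{val}(r) 4\pi r^2 dr} with the density integrated
#' numerically; oracle for [atomic_volume()].
#'
#' @inheritParams slater_potential
#' @return Volume, Bohr^3.
#' @export
oracle_atomic_volume <- function(q_val, s) {
  n_val <- -q_val
  f <- function(x) x^3 * n_val / (8 * pi * s^3) * exp(-x / s) * 4 * pi * x^2
  stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value
}

#' Gaussian-Gaussian interaction energy by nested quadrature
#'
#' Interaction of two spherical normal charge densities at separation `R`
#' via the bipolar reduction
#' \deqn{E(R) = \frac{2\pi}{R}\int_0^\infty r\,\rho_j(r)
#'   \left[\int_{|R-r|}^{R+r} t\,V_i(t)\,dt\right] dr}
#' (at `R = 0` the one-centre shell-theorem form is used). Oracle for
#' [qeq_hardness()] (as the `R = 0`, equal-width self-interaction) and
#' [qeq_pair_interaction()].
#'
#' @param sigma_i,sigma_j Gaussian standard deviations, Bohr.
#' @param R separation, Bohr (>= 0).
#' @return Interaction energy per unit charge product, Hartree/e^2.
#' @export
oracle_gaussian_interaction <- function(sigma_i, sigma_j, R) {
  rho_i <- function(x) (2 * pi * sigma_i^2)^(-3 / 2) * exp(-x^2 / (2 * sigma_i^2))
  rho_j <- function(x) (2 * pi * sigma_j^2)^(-3 / 2) * exp(-x^2 / (2 * sigma_j^2))
  v_i <- function(t) vapply(t, function(tt) quadrature_potential(rho_i, tt),
                            0.0)
  if (R < 1e-12) {
    f <- function(x) 4 * pi * x^2 * rho_j(x) * v_i(x)
    return(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
  }
  inner <- function(r) vapply(r, function(rr) {
    stats::integrate(function(t) t * v_i(t), abs(R - rr), R + rr,
                     rel.tol = 1e-10)$value
  }, 0.0)
  f <- function(r) r * rho_j(r) * inner(r)
  2 * pi / R * stats::integrate(f, 0, 8 * sigma_j, rel.tol = 1e-10)$value
}

## ---------------------------------------------------------------------------
## Fixture generation

.VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L, S = 2L)
.COV_RADius <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.03)  # Angstrom

#' Fixture-generation specification
#'
#' Defines a reproducible family of toy molecules and MM meshes. Defaults:
#' 2-10 atoms per molecule, heavy-atom palette weighted towards carbon, MM
#' charges of up to 1 e on a 3-12 Angstrom shell around the molecule
#' (mirroring the cutoff mesh used in embedding evaluations).
#'
#' @param seed integer RNG seed; the generated set is a pure function of the
#'   spec.
#' @param n_molecules number of molecules.
#' @param heavy_palette named weights over heavy elements C, N, O, S.
#' @param max_heavy maximum heavy atoms per molecule.
#' @param jitter coordinate jitter s.d., Angstrom.
#' @param mesh_n number of MM charges per mesh.
#' @param mesh_range radial shell for MM charges, Angstrom.
#' @param mesh_qmax maximum absolute MM charge, e.
#' @return An object of class `mlmm_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_molecules = 200L,
                         heavy_palette = c(C = 0.5, N = 0.2, O = 0.2, S = 0.1),
                         max_heavy = 3L, jitter = 0.03,
                         mesh_n = 25L, mesh_range = c(3, 12), mesh_qmax = 1) {
  stopifnot(n_molecules >= 1, max_heavy >= 1, all(mesh_range > 0),
            mesh_range[1] < mesh_range[2], mesh_qmax > 0,
            all(names(heavy_palette) %in% c("C", "N", "O", "S")))
  structure(list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
                 heavy_palette = heavy_palette / sum(heavy_palette),
                 max_heavy = as.integer(max_heavy), jitter = jitter,
                 mesh_n = as.integer(mesh_n), mesh_range = mesh_range,
                 mesh_qmax = mesh_qmax),
            class = "mlmm_fixture_spec")
}

.bond_length <- function(e1, e2) .COV_RADius[e1] + .COV_RADius[e2]

## one clash-free toy molecule: heavy-atom tree + hydrogens to fill valence,
## capped at 10 atoms
.make_one_molecule <- function(spec) {
  repeat {
    n_heavy <- sample.int(spec$max_heavy, 1)
    heavy <- sample(names(spec$heavy_palette), n_heavy, replace = TRUE,
                    prob = spec$heavy_palette)
    el <- heavy[1]; xyz <- matrix(0, 1, 3)
    parent_ok <- TRUE
    if (n_heavy > 1) for (k in 2:n_heavy) {
      deg <- vapply(seq_along(el), function(i)
        sum(sqrt(colSums((t(xyz) - xyz[i, ])^2)) < 2.2) - 1L, 0L)
      open <- which(.VALENCE[el] - deg > 0)
      if (!length(open)) { parent_ok <- FALSE; break }
      p <- if (length(open) == 1) open else sample(open, 1)
      b <- .bond_length(el[p], heavy[k])
      placed <- FALSE
      for (try in 1:60) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pos <- xyz[p, ] + b * u
        d <- sqrt(colSums((t(xyz) - pos)^2))
        if (all(d[-p] > 2.2) && d[p] > 0.7) {
          el <- c(el, heavy[k]); xyz <- rbind(xyz, pos); placed <- TRUE; break
        }
      }
      if (!placed) { parent_ok <- FALSE; break }
    }
    if (!parent_ok) next
    # hydrogens fill remaining valence
    n_heavy_now <- length(el)
    deg <- vapply(seq_len(n_heavy_now), function(i)
      sum(sqrt(colSums((t(xyz[seq_len(n_heavy_now), , drop = FALSE]) -
                          xyz[i, ])^2)) < 2.2) - 1L, 0L)
    ok <- TRUE
    for (i in seq_len(n_heavy_now)) {
      nh <- .VALENCE[el[i]] - deg[i]
      if (nh <= 0) next
      b <- .bond_length(el[i], "H")
      for (h in seq_len(nh)) {
        placed <- FALSE
        for (try in 1:80) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          pos <- xyz[i, ] + b * u
          d <- sqrt(colSums((t(xyz) - pos)^2))
          if (all(d[-i] > 0.95) && d[i] > 0.7) {
            el <- c(el, "H"); xyz <- rbind(xyz, pos); placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    if (length(el) > 10) {                       # cap size at 10 atoms
      hs <- which(el == "H")
      drop <- sample(hs, length(el) - 10)
      el <- el[-drop]; xyz <- xyz[-drop, , drop = FALSE]
    }
    if (length(el) < 2) next
    xyz <- xyz + matrix(stats::rnorm(3 * length(el), sd = spec$jitter),
                        ncol = 3)
    if (min(stats::dist(xyz)) < 0.7) next
    return(molecule(el, xyz, total_charge = 0L))
  }
}

#' Generate a reproducible set of toy molecules
#'
#' Tetrahedral-ish tree geometries built from covalent-radius bond lengths
#' with small Gaussian jitter; every pair of atoms is at least 0.7 Angstrom
#' apart. The set always covers hydrogen plus every element of the heavy
#' palette (tail molecules are regenerated until coverage holds).
#'
#' @param spec an [fixture_spec()].
#' @return List of [molecule()] objects, a pure function of the spec.
#' @export
make_molecules <- function(spec) {
  set.seed(spec$seed)
  mols <- lapply(seq_len(spec$n_molecules), function(i) .make_one_molecule(spec))
  need <- c("H", names(spec$heavy_palette)[spec$heavy_palette > 0])
  slot <- spec$n_molecules
  repeat {
    have <- unique(unlist(lapply(mols, `[[`, "elements")))
    miss <- setdiff(setdiff(need, "H"), have)   # H is always present
    if (!length(miss) || slot < 1) break
    # overwrite a tail molecule with one centred on a missing heavy element
    forced <- spec
    forced$heavy_palette <- stats::setNames(1, miss[1])
    forced$max_heavy <- 1L
    mols[[slot]] <- .make_one_molecule(forced)
    slot <- slot - 1L
  }
  mols
}

#' Generate an MM point-charge mesh around a molecule
#'
#' Charges are placed so that the distance to the closest atom lies in
#' `spec$mesh_range`, with charges uniform in `[-q_max, q_max]`.
#'
#' @param mol an [molecule()].
#' @param spec an [fixture_spec()] (mesh fields used).
#' @param n number of charges (defaults to `spec$mesh_n`).
#' @return An [mm_charges()] object.
#' @export
make_mesh <- function(mol, spec = fixture_spec(), n = spec$mesh_n) {
  ctr <- colMeans(mol$xyz)
  pos <- matrix(0, 0, 3)
  while (nrow(pos) < n) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    r <- stats::runif(1, spec$mesh_range[1], spec$mesh_range[2] + 2)
    p <- ctr + r * u
    dmin <- min(sqrt(colSums((t(mol$xyz) - p)^2)))
    if (dmin >= spec$mesh_range[1] && dmin <= spec$mesh_range[2])
      pos <- rbind(pos, p)
  }
  mm_charges(pos, stats::runif(n, -spec$mesh_qmax, spec$mesh_qmax))
}

#' Ground-truth parameter set for synthetic reference data
#'
#' Physically plausible defaults: core charges Z minus the noble-gas core
#' electron count, MBIS-scale valence widths and Mulliken-scale
#' electronegativities in atomic units, polarizability/volume ratios chosen
#' so molecular alphas land in the usual organic range, and Thole's
#' exponential-form damping constant.
#'
#' @param q_core named per-element core charges, e.
#' @param s_mean named per-element mean valence widths, Bohr.
#' @param chi_mean named per-element mean electronegativities, Hartree/e.
#' @param s_mod,chi_mod relative modulation amplitude of `s`/`chi` with the
#'   soft coordination count.
#' @param a_qeq QEq width scaling factor (sigma = a_qeq * s).
#' @param k_z named per-element polarizability/volume ratios.
#' @param a_thole Thole damping factor.
#' @param cn_ref named per-element reference coordination numbers (the
#'   modulation is `tanh(cn - cn_ref)`).
#' @param basis_threshold IVM variance threshold used to pick the
#'   representative environments that carry the ground-truth basis values.
#' @return An object of class `mlmm_ground_truth`.
#' @export
ground_truth <- function(
    q_core = c(H = 1, C = 4, N = 5, O = 6, S = 6),
    s_mean = c(H = 0.45, C = 0.62, N = 0.56, O = 0.50, S = 0.85),
    chi_mean = c(H = 0.26, C = 0.30, N = 0.34, O = 0.40, S = 0.31),
    s_mod = 0.04, chi_mod = 0.10,
    a_qeq = 1.5,
    k_z = c(H = 0.55, C = 0.21, N = 0.14, O = 0.12, S = 0.09),
    a_thole = 0.572,
    cn_ref = c(H = 1, C = 4, N = 3, O = 2, S = 2),
    basis_threshold = 0.05) {
  stopifnot(all(a_qeq > 0), a_thole > 0, all(k_z > 0), all(s_mean > 0),
            basis_threshold > 0)
  structure(list(q_core = q_core, s_mean = s_mean, chi_mean = chi_mean,
                 s_mod = s_mod, chi_mod = chi_mod, a_qeq = a_qeq,
                 k_z = k_z, a_thole = a_thole, cn_ref = cn_ref,
                 basis_threshold = basis_threshold),
            class = "mlmm_ground_truth")
}

#' Soft coordination count
#'
#' \eqn{cn_i = \sum_{j \ne i} [1 + \exp((d_{ij} - r_0)/w)]^{-1}}: a smooth,
#' rotation-invariant measure of how crowded each atomic environment is. The
#' synthetic ground truth modulates widths and electronegativities through
#' this quantity.
#'
#' @param mol an [molecule()].
#' @param r0 switching distance, Angstrom.
#' @param w switching width, Angstrom.
#' @return Numeric per-atom coordination counts.
#' @export
coordination_count <- function(mol, r0 = 1.8, w = 0.15) {
  n <- n_atoms(mol)
  d <- as.matrix(stats::dist(mol$xyz))
  cn <- rowSums(1 / (1 + exp((d - r0) / w))) - 1 / (1 + exp(-r0 / w))
  as.numeric(cn)
}

## per-atom ground-truth property functions for a set of molecules.
## The truth is a "basis values atop element means" construction: at a set of
## representative environments (IVM on the generated data) the properties
## take coordination-modulated values, and everywhere else they are the
## regular-GPR kernel interpolation of those basis values -- a smooth,
## rotation-invariant function of the local environment.
.truth_property_functions <- function(mols, truth, soap) {
  X <- do.call(rbind, lapply(mols, soap_matrix, config = soap))
  el <- unlist(lapply(mols, `[[`, "elements"))
  attr(X, "center_elements") <- el
  attr(X, "config_key") <- soap$key
  iv <- ivm_select(X, zeta = 2, threshold = truth$basis_threshold)
  W <- .gpr_interp_map(X, iv$selected, zeta = 2, jitter = 1e-8)$W
  cn <- unlist(lapply(mols, coordination_count))
  bsel <- iv$selected
  mod_b <- tanh(cn[bsel] - truth$cn_ref[el[bsel]])
  s_basis <- truth$s_mean[el[bsel]] * (1 + truth$s_mod * mod_b)
  chi_basis <- truth$chi_mean[el[bsel]] * (1 + truth$chi_mod * mod_b)
  list(s = drop(W %*% s_basis), chi = drop(W %*% chi_basis),
       basis = bsel, s_basis = unname(s_basis),
       chi_basis = unname(chi_basis))
}

#' Generate reference training tables from a ground truth
#'
#' Widths and electronegativities are smooth environment functions (kernel
#' interpolation of coordination-modulated basis values), charges come from
#' the exact QEq solve under the true parameters, and molecular dipolar
#' polarizability tensors from the exact Thole solve with volume-based
#' alphas. Optional Gaussian noise emulates the reference-data error scale of
#' a real density partitioning (typically 0.003 Bohr on `s`, 0.02 e on
#' charges); charge noise is centred per molecule so charge sums stay exactly
#' at the molecular total.
#'
#' @param mols list of [molecule()] objects.
#' @param truth an [ground_truth()].
#' @param noise_s,noise_q noise standard deviations (Bohr, e); both default
#'   to zero for exact self-consistency.
#' @param soap descriptor configuration for the ground-truth environment
#'   functions.
#' @return A list with `atoms` (data.frame: molecule_id, element, x, y, z,
#'   q_core, q_val, s), `polarizabilities` (data.frame: molecule_id, axx,
#'   axy, axz, ayy, ayz, azz) and `truth_values` (the noise-free per-atom
#'   `s`, `chi` and charges actually used).
#' @export
make_reference_tables <- function(mols, truth = ground_truth(),
                                  noise_s = 0, noise_q = 0,
                                  soap = soap_config()) {
  fn <- .truth_property_functions(mols, truth, soap)
  if (any(fn$s <= 0))
    stop("ground truth produced non-positive widths; lower s_mod",
         call. = FALSE)
  atoms <- vector("list", length(mols))
  pols <- matrix(0, length(mols), 6)
  offset <- 0L
  q_true_all <- numeric(length(fn$s))
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    idx <- offset + seq_len(n_atoms(mol)); offset <- offset + n_atoms(mol)
    pr <- list(s = fn$s[idx], chi = fn$chi[idx])
    sys <- qeq_system(pr$chi, truth$a_qeq * pr$s, to_bohr(mol$xyz),
                      q_tot = mol$total_charge)
    q <- solve_qeq(sys)$charges
    q_true_all[idx] <- q
    q_core <- truth$q_core[mol$elements]
    q_val <- q - q_core
    a <- volumes_to_alphas(atomic_volume(q_val, pr$s), mol$elements,
                           truth$k_z)
    am <- molecular_polarizability(
      thole_system(a, to_bohr(mol$xyz), truth$a_thole))
    pols[m, ] <- c(am[1, 1], am[1, 2], am[1, 3], am[2, 2], am[2, 3], am[3, 3])
    s_out <- pr$s + stats::rnorm(n_atoms(mol), sd = noise_s)
    dq <- stats::rnorm(n_atoms(mol), sd = noise_q)
    dq <- dq - mean(dq)                  # keep exact charge conservation
    atoms[[m]] <- data.frame(
      molecule_id = m, element = mol$elements,
      x = mol$xyz[, 1], y = mol$xyz[, 2], z = mol$xyz[, 3],
      q_core = unname(q_core), q_val = unname(q_val + dq),
      s = unname(s_out), stringsAsFactors = FALSE)
  }
  list(atoms = do.call(rbind, atoms),
       polarizabilities = data.frame(
         molecule_id = seq_along(mols),
         axx = pols[, 1], axy = pols[, 2], axz = pols[, 3],
         ayy = pols[, 4], ayz = pols[, 5], azz = pols[, 6]),
       truth_values = list(s = fn$s, chi = fn$chi, q = q_true_all,
                           basis = fn$basis))
}
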