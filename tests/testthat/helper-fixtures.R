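# Shared fixtures built in code. Geometry in Angstrom, physics in a.u.

water_fixture <- function() {
  molecule(c("O", "H", "H"),
           rbind(c(0.000, 0.000, 0.117),
                 c(0.000, 0.757, -0.469),
                 c(0.000, -0.757, -0.469)))
}

# neutral Slater parameter set for the water fixture (sums to 0)
water_density <- function(mol = water_fixture()) {
  static_density_model(mol,
                       q_core = c(6, 1, 1),
                       q_val = c(-6.6, -0.7, -0.7),
                       s = c(0.50, 0.45, 0.45))
}

# four charges on a tetrahedron at distance d from the origin
tetrahedral_mesh <- function(d = 5, q = c(-0.8, 0.4, 0.4, -0.3)) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  mm_charges(d * dirs, q)
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3))) * sample(c(-1, 1), 1)
}

rotate_molecule <- function(mol, R, shift = c(0, 0, 0)) {
  molecule(mol$elements, sweep(mol$xyz %*% t(R), 2, shift, "+"),
           total_charge = mol$total_charge)
}

# small deterministic molecule set for descriptor/GPR tests
small_molecule_set <- function(n = 20, seed = 11) {
  make_molecules(fixture_spec(seed = seed, n_molecules = n))
}

soap_stack <- function(mols, cfg = soap_config()) {
  X <- do.call(rbind, lapply(mols, soap_matrix, config = cfg))
  attr(X, "center_elements") <- unlist(lapply(mols, `[[`, "elements"))
  attr(X, "config_key") <- cfg$key
  X
}

# independent dense oracle for the same regularized objective, solved by
# explicit (pseudo-inverted) normal equations in long double via SVD
dense_gpr_oracle <- function(Knm, Kmm, y, elements, noise, ridge = 1e-10) {
  lev <- sort(unique(elements))
  D <- outer(elements, lev, `==`) + 0
  m <- ncol(Knm); p <- length(lev)
  A <- cbind(Knm, D)
  Nmat <- crossprod(A) + diag(ridge, m + p)
  Nmat[seq_len(m), seq_len(m)] <- Nmat[seq_len(m), seq_len(m)] + noise * Kmm
  sv <- svd(Nmat)
  sol <- sv$v %*% (t(sv$u) %*% crossprod(A, y) / sv$d)
  list(weights = sol[seq_len(m)],
       intercepts = stats::setNames(sol[m + seq_len(p)], lev))
}

# brute-force greedy IVM oracle: recompute every posterior variance from
# scratch with dense linear algebra at each step
ivm_oracle <- function(K, threshold, jitter = 1e-8) {
  n <- nrow(K)
  selected <- integer(0)
  repeat {
    v <- vapply(seq_len(n), function(i) {
      if (!length(selected)) return(1)
      ks <- K[selected, i]
      1 - drop(ks %*% solve(K[selected, selected, drop = FALSE] +
                              diag(jitter, length(selected)), ks))
    }, 0.0)
    s <- which.max(v)
    if (length(selected) > 0 && v[s] < threshold) break
    selected <- c(selected, s)
  }
  selected
}
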