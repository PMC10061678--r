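# independent objective for the induction model, built from the exported
# tensor (used to check variational properties of the solver)
thole_objective <- function(sys, mu, fields) {
  n <- nrow(mu)
  e <- -sum(mu * fields) + sum(rowSums(mu^2) / (2 * sys$alpha))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    e <- e - drop(mu[i, ] %*% damped_dipole_tensor(sys, i, j) %*% mu[j, ])
  e
}

test_that("mm_fields gives Coulomb fields and superposes", {
  mol <- molecule("O", rbind(c(0, 0, 0)))
  d_ang <- 4; d <- to_bohr(d_ang)
  mm <- mm_charges(rbind(c(0, 0, d_ang)), 0.5)
  E <- mm_fields(mol, mm)
  expect_equal(E[1, ], c(0, 0, -0.5 / d^2), tolerance = 1e-12)
  # opposite charges symmetric about the atom: fields add, potentials cancel
  mm2 <- mm_charges(rbind(c(0, 0, d_ang), c(0, 0, -d_ang)), c(0.5, -0.5))
  E2 <- mm_fields(mol, mm2)
  expect_equal(E2[1, ], 2 * E[1, ], tolerance = 1e-12)
  empty <- mm_charges(matrix(0, 0, 3), numeric(0))
  expect_equal(mm_fields(mol, empty), matrix(0, 1, 3))
})

test_that("damped tensor is symmetric, switches off, and is finite at contact", {
  sys <- thole_system(c(1, 1), rbind(c(0, 0, 0), c(0, 0, 20)), 0.39)
  Tij <- damped_dipole_tensor(sys, 1, 2)
  expect_identical(Tij, t(damped_dipole_tensor(sys, 2, 1)))
  # large reduced distance: damping is off
  r <- 20
  bare <- 3 * tcrossprod(c(0, 0, r)) / r^5 - diag(3) / r^3
  expect_lt(max(abs(Tij - bare)) / max(abs(bare)), 1e-10)
  # near-contact: matches the independent series expansion of the damping
  a <- 0.45; al <- c(2, 3)
  u <- 0.01; r0 <- u * (al[1] * al[2])^(1 / 6)
  sys0 <- thole_system(al, rbind(c(0, 0, 0), c(0, 0, r0)), a)
  T0 <- damped_dipole_tensor(sys0, 1, 2)
  x <- a * u^3
  l3 <- x - x^2 / 2 + x^3 / 6 - x^4 / 24
  l5 <- x^2 / 2 - x^3 / 3 + x^4 / 8 - x^5 / 30
  T_series <- l5 * 3 * tcrossprod(c(0, 0, r0)) / r0^5 - l3 * diag(3) / r0^3
  expect_equal(T0, T_series, tolerance = 1e-10)
  expect_true(all(is.finite(T0)))
  expect_error(damped_dipole_tensor(sys, 2, 2), "i != j")
})

test_that("single-site solutions follow the closed forms", {
  al <- 5
  sys <- thole_system(al, rbind(c(0, 0, 0)), 0.39)
  E <- rbind(c(0, 0.02, -0.01))
  dip <- solve_dipoles(sys, E)
  expect_equal(dip$mu, al * E, tolerance = 1e-12)
  expect_equal(polarization_cost(sys, dip), al * sum(E^2) / 2,
               tolerance = 1e-12)
  expect_equal(solve_dipoles(sys, rbind(c(0, 0, 0)))$mu, matrix(0, 1, 3))
  expect_equal(molecular_polarizability(sys), al * diag(3),
               tolerance = 1e-12)
})

test_that("two identical atoms reproduce the axial closed form in the undamped limit", {
  al <- 2; r <- 6
  # enormous damping factor: exp(-a u^3) is identically 0, tensor undamped
  sys <- thole_system(c(al, al), rbind(c(0, 0, 0), c(0, 0, r)), 1e7)
  mp <- molecular_polarizability(sys)
  expect_equal(mp[3, 3], 2 * al / (1 - 2 * al / r^3), tolerance = 1e-8)
  expect_equal(mp[1, 1], 2 * al / (1 + al / r^3), tolerance = 1e-8)
  # direct 6x6 solve oracle for a field along the bond
  A6 <- diag(rep(1 / al, 6))
  Tij <- damped_dipole_tensor(sys, 1, 2)
  A6[1:3, 4:6] <- -Tij; A6[4:6, 1:3] <- -t(Tij)
  mu6 <- solve(A6, rep(c(0, 0, 1), 2))
  dip <- solve_dipoles(sys, rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(as.numeric(t(dip$mu)), mu6, tolerance = 1e-10)
})

test_that("solved dipoles are variational minimizers with the energy identity", {
  set.seed(11)
  pos <- matrix(runif(15, -2.5, 2.5), 5)
  sys <- thole_system(runif(5, 1, 6), pos, 0.572)
  fields <- matrix(rnorm(15, sd = 0.02), 5)
  dip <- solve_dipoles(sys, fields)
  e0 <- thole_objective(sys, dip$mu, fields)
  # energy identity at the minimum
  expect_equal(e0, -0.5 * sum(dip$mu * fields), tolerance = 1e-10)
  # any perturbation strictly increases the objective
  for (k in 1:10) {
    d <- matrix(rnorm(15), 5); d <- 1e-4 * d / sqrt(sum(d^2))
    expect_gt(thole_objective(sys, dip$mu + d, fields), e0)
  }
  # residual of the linear system
  A <- mlmm:::.thole_relay(sys)
  expect_lt(max(abs(A %*% as.numeric(t(dip$mu)) - as.numeric(t(fields)))),
            1e-10)
  # brute-force polarization cost
  expect_equal(polarization_cost(sys, dip),
               sum(sapply(1:5, function(i)
                 sum(dip$mu[i, ]^2) / (2 * sys$alpha[i]))),
               tolerance = 1e-12)
})

test_that("induced potential has dipolar form and decay", {
  sys <- thole_system(3, rbind(c(0, 0, 0)), 0.39)
  mu <- rbind(c(0, 0, 0.1))
  d <- 8
  expect_equal(induced_potential(sys, mu, rbind(c(0, 0, d))), 0.1 / d^2,
               tolerance = 1e-12)
  expect_equal(induced_potential(sys, 0 * mu, rbind(c(0, 0, d))), 0)
  v1 <- induced_potential(sys, mu, rbind(c(0, 0, d)))
  v2 <- induced_potential(sys, mu, rbind(c(0, 0, 2 * d)))
  expect_equal(v1 / v2, 4, tolerance = 1e-3)
})

test_that("molecular polarizability is equivariant and matches finite differences", {
  set.seed(12)
  pos <- matrix(runif(12, -2, 2), 4)
  al <- runif(4, 1, 5)
  sys <- thole_system(al, pos, 0.572)
  mp <- molecular_polarizability(sys)
  expect_identical(mp, t(mp))
  # rotation equivariance
  R <- random_rotation()
  mp_rot <- molecular_polarizability(thole_system(al, pos %*% t(R), 0.572))
  expect_equal(mp_rot, R %*% mp %*% t(R), tolerance = 1e-10)
  # finite-difference oracle: total dipole under +-1e-4 uniform fields
  h <- 1e-4
  fd <- matrix(0, 3, 3)
  for (k in 1:3) {
    Ep <- matrix(0, 4, 3); Ep[, k] <- h
    mu_p <- colSums(solve_dipoles(sys, Ep)$mu)
    mu_m <- colSums(solve_dipoles(sys, -Ep)$mu)
    fd[, k] <- (mu_p - mu_m) / (2 * h)
  }
  expect_equal(mp, (fd + t(fd)) / 2, tolerance = 1e-6)
  # isotropic sum rule for well-separated atoms
  far <- thole_system(al, cbind(150 * (0:3), 0, 0), 0.572)
  mp_far <- molecular_polarizability(far)
  expect_equal(mp_far, sum(al) * diag(3), tolerance = 1e-6 * sum(al))
})

test_that("the polarization catastrophe is reported as a physics error", {
  # two big polarizabilities close together with damping switched off
  # (large a_thole means exp(-a u^3) ~ 0, i.e. the bare tensor)
  sys <- thole_system(c(10, 10), rbind(c(0, 0, 0), c(0, 0, 1.2)), 50)
  expect_error(solve_dipoles(sys, matrix(0.01, 2, 3)),
               "polarization catastrophe.*1-2")
})

test_that("volumes_to_alphas is an elementwise product with per-element ratios", {
  vols <- c(5.5, 57, 45)
  els <- c("H", "C", "O")
  k <- c(H = 0.5, C = 0.2, O = 0.12)
  expect_equal(volumes_to_alphas(vols, els, k),
               c(0.5 * 5.5, 0.2 * 57, 0.12 * 45))
  expect_equal(volumes_to_alphas(vols, els, k * 2),
               2 * volumes_to_alphas(vols, els, k))
  expect_error(volumes_to_alphas(vols, c("H", "C", "S"), k), "missing")
})
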