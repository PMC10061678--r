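# one small trained model shared by the engine tests
engine_fix <- local({
  spec <- fixture_spec(seed = 19, n_molecules = 25)
  mols <- make_molecules(spec)
  truth <- ground_truth()
  tabs <- make_reference_tables(mols, truth)
  model <- suppressWarnings(
    train_full(tabs$atoms, tabs$polarizabilities,
               train_config(adam_iters = 150)))
  list(spec = spec, mols = mols, truth = truth, model = model)
})

test_that("an empty mesh gives exactly zero energies", {
  mol <- engine_fix$mols[[1]]
  res <- predict_embedding(mol, mm_charges(matrix(0, 0, 3), numeric(0)),
                           engine_fix$model)
  expect_identical(res$e_static, 0)
  expect_identical(res$e_induced_interaction, 0)
  expect_identical(res$e_pol, 0)
  expect_identical(res$e_total, 0)
  expect_equal(sum(res$charges), mol$total_charge, tolerance = 1e-10)
})

test_that("a single atom with one far charge composes the closed forms", {
  mol <- molecule("S", rbind(c(0, 0, 0)))
  d_ang <- 6; q <- -0.75
  mm <- mm_charges(rbind(c(0, 0, d_ang)), q)
  model <- engine_fix$model
  res <- predict_embedding(mol, mm, model)
  d <- to_bohr(d_ang)
  e_static <- q * slater_potential(model$q_core[["S"]],
                                   res$charges[1] - model$q_core[["S"]],
                                   res$widths[1], d)
  expect_equal(res$e_static, hartree_to_kcalmol(e_static), tolerance = 1e-10)
  # induced part: mu = alpha E, interaction + cost = -1/2 alpha E^2
  alpha <- res$alphas[1]
  E <- q / d^2
  expect_equal(res$e_induced_interaction + res$e_pol,
               hartree_to_kcalmol(-0.5 * alpha * E^2), tolerance = 1e-10)
  expect_equal(res$e_pol, hartree_to_kcalmol(0.5 * alpha * E^2),
               tolerance = 1e-10)
})

test_that("predict_embedding equals the hand-composed module pipeline", {
  model <- engine_fix$model
  mol <- engine_fix$mols[[3]]
  set.seed(61)
  mm <- make_mesh(mol, engine_fix$spec, n = 15)
  res <- predict_embedding(mol, mm, model)
  # hand-composed oracle from the module-level operations
  X <- soap_matrix(mol, model$soap)
  s <- predict(model$width_model, X, elements = mol$elements)
  chi <- predict(model$chi_model, X, elements = mol$elements)
  q_core <- unname(model$q_core[mol$elements])
  q <- solve_qeq(qeq_system(chi, model$a_qeq * s, to_bohr(mol$xyz), 0))$charges
  dens <- static_density_model(mol, q_core, q - q_core, s)
  e_static <- static_embedding_energy(dens, mol, mm)
  alphas <- volumes_to_alphas(atomic_volume(q - q_core, s), mol$elements,
                              model$k_z)
  tsys <- thole_system(alphas, to_bohr(mol$xyz), model$a_thole)
  dip <- solve_dipoles(tsys, mm_fields(mol, mm))
  e_ind <- sum(mm$charges *
                 induced_potential(tsys, dip, to_bohr(mm$positions)))
  e_pol <- polarization_cost(tsys, dip)
  expect_equal(res$e_static, hartree_to_kcalmol(e_static), tolerance = 1e-10)
  expect_equal(res$e_induced_interaction, hartree_to_kcalmol(e_ind),
               tolerance = 1e-10)
  expect_equal(res$e_pol, hartree_to_kcalmol(e_pol), tolerance = 1e-10)
  expect_equal(res$e_total,
               res$e_static + res$e_induced_interaction + res$e_pol,
               tolerance = 1e-10)
  expect_gte(res$e_pol, 0)
  # the charge-potential and dipole-field forms of the induced term agree
  expect_equal(e_ind, -sum(dip$mu * dip$fields), tolerance = 1e-10)
})

test_that("the variational induction convention gives the minimized objective", {
  model <- engine_fix$model
  mol <- engine_fix$mols[[5]]
  set.seed(62)
  mm <- make_mesh(mol, engine_fix$spec, n = 10)
  res_p <- predict_embedding(mol, mm, model, induction = "paper")
  res_v <- predict_embedding(mol, mm, model, induction = "variational")
  expect_equal(res_p$e_static, res_v$e_static)
  expect_equal(res_p$e_pol, res_v$e_pol)
  # variational total induced part = -1/2 sum mu.E
  X <- res_v$e_induced_interaction + res_v$e_pol
  fields <- mm_fields(mol, mm)
  expect_equal(X, hartree_to_kcalmol(-0.5 * sum(res_v$dipoles * fields)),
               tolerance = 1e-10)
  # conventions agree for a single polarizable site
  m1 <- molecule("O", rbind(c(0, 0, 0)))
  mm1 <- mm_charges(rbind(c(0, 0, 5)), 0.4)
  r1p <- predict_embedding(m1, mm1, model, induction = "paper")
  r1v <- predict_embedding(m1, mm1, model, induction = "variational")
  expect_equal(r1p$e_total, r1v$e_total, tolerance = 1e-12)
})

test_that("energies are invariant under joint rigid motion and MM reordering", {
  model <- engine_fix$model
  mol <- engine_fix$mols[[7]]
  set.seed(63)
  mm <- make_mesh(mol, engine_fix$spec, n = 12)
  res <- predict_embedding(mol, mm, model)
  R <- random_rotation(); shift <- c(1.3, -2.0, 0.4)
  mol_r <- rotate_molecule(mol, R, shift)
  mm_r <- mm_charges(sweep(mm$positions %*% t(R), 2, shift, "+"),
                     mm$charges)
  res_r <- predict_embedding(mol_r, mm_r, model)
  expect_lt(abs(res_r$e_total - res$e_total), 1e-8)
  # permuting the MM charge order changes nothing
  perm <- sample(n_charges(mm))
  mm_p <- mm_charges(mm$positions[perm, ], mm$charges[perm])
  res_p <- predict_embedding(mol, mm_p, model)
  expect_equal(res_p$e_total, res$e_total, tolerance = 1e-12)
})

test_that("static energy is mesh-additive and components scale correctly", {
  model <- engine_fix$model
  mol <- engine_fix$mols[[9]]
  set.seed(64)
  mm1 <- make_mesh(mol, engine_fix$spec, n = 8)
  mm2 <- make_mesh(mol, engine_fix$spec, n = 8)
  mm_union <- mm_charges(rbind(mm1$positions, mm2$positions),
                         c(mm1$charges, mm2$charges))
  r1 <- predict_embedding(mol, mm1, model)
  r2 <- predict_embedding(mol, mm2, model)
  ru <- predict_embedding(mol, mm_union, model)
  expect_equal(ru$e_static, r1$e_static + r2$e_static, tolerance = 1e-10)
  # induced part is quadratic, not additive
  expect_gt(abs(ru$e_induced_interaction + ru$e_pol -
                  (r1$e_induced_interaction + r1$e_pol +
                     r2$e_induced_interaction + r2$e_pol)), 1e-8)
  # charge scaling: static linear, induced quadratic
  cfac <- 1.7
  rs <- predict_embedding(mol, mm_charges(mm1$positions,
                                          cfac * mm1$charges), model)
  expect_equal(rs$e_static, cfac * r1$e_static, tolerance = 1e-10)
  expect_equal(rs$e_induced_interaction + rs$e_pol,
               cfac^2 * (r1$e_induced_interaction + r1$e_pol),
               tolerance = 1e-10 * abs(r1$e_total) * cfac^2 + 1e-10)
})

test_that("the total energy of a distant unit charge decays at least dipolarly", {
  model <- engine_fix$model
  mol <- engine_fix$mols[[2]]
  ds <- 2^(4:8)  # 16 ... 256 Angstrom
  e <- vapply(ds, function(d) {
    mm <- mm_charges(rbind(c(0, 0, d)), 1)
    abs(predict_embedding(mol, mm, model)$e_total)
  }, 0.0)
  ratios <- e[-length(e)] / e[-1]
  expect_true(all(ratios > 3.5))   # halving 1/d^2 quarters the energy
})

test_that("evaluation reports raw and mean-removed RMSE with oracle agreement", {
  model <- engine_fix$model
  set.seed(65)
  snaps <- lapply(engine_fix$mols[1:6], function(mol)
    list(mol = mol, mm = make_mesh(mol, engine_fix$spec, n = 10)))
  preds <- vapply(snaps, function(sn)
    predict_embedding(sn$mol, sn$mm, model)$e_total, 0.0)
  # references equal to the predictions: both RMSEs vanish
  for (i in seq_along(snaps)) snaps[[i]]$reference <- preds[i]
  ev0 <- evaluate_embedding(snaps, model)
  expect_equal(ev0$rmse, 0, tolerance = 1e-12)
  expect_equal(ev0$rmse_after_mean_removal, 0, tolerance = 1e-12)
  # constant offset: raw RMSE |c|, mean-removed 0
  cst <- 3.7
  for (i in seq_along(snaps)) snaps[[i]]$reference <- preds[i] - cst
  ev1 <- evaluate_embedding(snaps, model)
  expect_equal(ev1$rmse, cst, tolerance = 1e-10)
  expect_equal(ev1$rmse_after_mean_removal, 0, tolerance = 1e-10)
  # random references: matches a direct two-pass oracle
  set.seed(66)
  refs <- preds + rnorm(6)
  for (i in seq_along(snaps)) snaps[[i]]$reference <- refs[i]
  ev2 <- evaluate_embedding(snaps, model)
  d <- preds - refs
  expect_equal(ev2$rmse, sqrt(mean(d^2)), tolerance = 1e-12)
  expect_equal(ev2$rmse_after_mean_removal, sqrt(mean((d - mean(d))^2)),
               tolerance = 1e-12)
  expect_lte(ev2$rmse_after_mean_removal, ev2$rmse)
  expect_error(evaluate_embedding(snaps[1], model), "length|>= 2|not")
})

test_that("prediction refuses molecules outside the model's element coverage", {
  model <- engine_fix$model
  model$q_core <- model$q_core[c("H", "C")]
  mol <- molecule(c("O", "H", "H"), water_fixture()$xyz)
  expect_error(predict_embedding(mol, tetrahedral_mesh(), model),
               "does not cover.*O")
})
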