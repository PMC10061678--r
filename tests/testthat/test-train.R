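# small training fixture shared across blocks (built once per file)
train_fix <- local({
  spec <- fixture_spec(seed = 7, n_molecules = 30)
  mols <- make_molecules(spec)
  truth <- ground_truth()
  tabs <- make_reference_tables(mols, truth)
  list(spec = spec, mols = mols, truth = truth, tabs = tabs)
})

test_that("core charges are per-element means and demand full coverage", {
  rec <- data.frame(molecule_id = c(1, 1, 1, 2, 2),
                    element = c("C", "C", "H", "O", "H"),
                    x = 0, y = 0, z = 1:5,
                    q_core = c(4.1, 3.9, 1.0, 6.0, 0.9),
                    q_val = c(-4.1, -3.9, -1.0, -6.0, -0.9),
                    s = 0.5)
  out <- fit_core_charges(rec, elements = c("H", "C", "O"))
  expect_equal(out, c(H = 0.95, C = 4.0, O = 6.0))
  expect_error(fit_core_charges(rec), "no reference atoms.*N.*S|N, S")
  # identical records give back the constant
  rec2 <- rec[rec$element == "O", ]
  expect_equal(fit_core_charges(rec2, elements = "O"), c(O = 6))
})

test_that("the QEq adjoint gradient matches central finite differences", {
  tabs <- train_fix$tabs
  at <- tabs$atoms[tabs$atoms$molecule_id <= 6, ]
  mi <- mlmm:::.table_molecules(at)
  cache <- mlmm:::.qeq_train_cache(at, mi, at$s)
  n_tot <- nrow(at)
  set.seed(41)
  chi <- runif(n_tot, 0.2, 0.5)
  a <- 1.3
  ev <- mlmm:::.qeq_loss(cache, chi, a, n_tot)
  h <- 1e-6
  for (i in sample(n_tot, 5)) {
    cp <- chi; cp[i] <- cp[i] + h
    cm <- chi; cm[i] <- cm[i] - h
    fd <- (mlmm:::.qeq_loss(cache, cp, a, n_tot)$loss -
             mlmm:::.qeq_loss(cache, cm, a, n_tot)$loss) / (2 * h)
    expect_equal(ev$g_chi[i], fd, tolerance = 1e-5)
  }
  hl <- 1e-6
  fd_a <- (mlmm:::.qeq_loss(cache, chi, a * exp(hl), n_tot)$loss -
             mlmm:::.qeq_loss(cache, chi, a * exp(-hl), n_tot)$loss) / (2 * hl)
  expect_equal(ev$g_loga, fd_a, tolerance = 1e-5)
})

test_that("train_full recovers the generating parameters on noise-free data", {
  tabs <- train_fix$tabs
  truth <- train_fix$truth
  model <- train_full(tabs$atoms, tabs$polarizabilities,
                      train_config(adam_iters = 200))
  expect_equal(model$q_core, truth$q_core[names(model$q_core)],
               tolerance = 1e-10)
  expect_lt(model$diagnostics$charge_rmse, 1e-3)
  expect_equal(model$a_qeq, truth$a_qeq, tolerance = 1e-3)
  expect_equal(unname(model$k_z[names(truth$k_z)]), unname(truth$k_z),
               tolerance = 1e-2)
  expect_equal(model$a_thole, truth$a_thole, tolerance = 1e-2)
})

test_that("charge noise degrades the fit by no more than its own scale", {
  sigma_n <- 0.01
  set.seed(43)
  tabs_n <- make_reference_tables(train_fix$mols, train_fix$truth,
                                  noise_q = sigma_n)
  model <- train_full(tabs_n$atoms, tabs_n$polarizabilities,
                      suppressWarnings(train_config(adam_iters = 150)))
  expect_lt(model$diagnostics$charge_rmse, 2 * sigma_n)
})

test_that("k_Z rescales linearly for one-element molecules at large separation", {
  # two far-apart S-H-free sulfur atoms: damping interplay is negligible
  mols <- list(molecule(c("S", "S"), rbind(c(0, 0, 0), c(30, 0, 0))))
  truth <- train_fix$truth
  tab <- make_reference_tables(mols, truth)
  c_scale <- 1.7
  tab2 <- tab
  tab2$polarizabilities[, -1] <- tab$polarizabilities[, -1] * c_scale
  vols <- atomic_volume(tab$atoms$q_val, tab$atoms$s)
  f1 <- suppressWarnings(
    fit_polarizability_params(tab$atoms, tab$polarizabilities, vols,
                              train_config()))
  f2 <- suppressWarnings(
    fit_polarizability_params(tab2$atoms, tab2$polarizabilities, vols,
                              train_config()))
  expect_equal(unname(f2$k_z["S"] / f1$k_z["S"]), c_scale,
               tolerance = 1e-4)
})

test_that("a_thole is unidentifiable from single-atom molecules", {
  mols <- list(molecule("O", rbind(c(0, 0, 0))),
               molecule("S", rbind(c(0, 0, 0))))
  tab <- make_reference_tables(mols, train_fix$truth)
  vols <- atomic_volume(tab$atoms$q_val, tab$atoms$s)
  expect_warning(
    f <- fit_polarizability_params(tab$atoms, tab$polarizabilities, vols,
                                   train_config(a_thole_init = 0.77)),
    "unidentifiable")
  expect_false(f$identifiable)
  expect_equal(f$a_thole, 0.77)
})

test_that("retraining with the same configuration is deterministic", {
  tabs <- train_fix$tabs
  at <- tabs$atoms[tabs$atoms$molecule_id <= 10, ]
  po <- tabs$polarizabilities[tabs$polarizabilities$molecule_id <= 10, ]
  cfg <- suppressWarnings(train_config(adam_iters = 40))
  m1 <- suppressWarnings(train_full(at, po, cfg))
  m2 <- suppressWarnings(train_full(at, po, cfg))
  expect_equal(m1$a_qeq, m2$a_qeq, tolerance = 1e-12)
  expect_equal(m1$width_model$weights, m2$width_model$weights,
               tolerance = 1e-12)
  expect_equal(m1$chi_model$weights, m2$chi_model$weights, tolerance = 1e-12)
  expect_equal(m1$k_z, m2$k_z, tolerance = 1e-12)
})

test_that("exclusion lists drop molecules and stage errors name the stage", {
  tabs <- train_fix$tabs
  at <- tabs$atoms[tabs$atoms$molecule_id <= 8, ]
  po <- tabs$polarizabilities[tabs$polarizabilities$molecule_id <= 8, ]
  # excluding the only sulfur-containing molecules must fail loudly at stage 1
  s_mols <- unique(at$molecule_id[at$element == "S"])
  if (length(s_mols) && length(s_mols) < 8) {
    expect_error(
      suppressWarnings(
        train_full(at, po, train_config(adam_iters = 10,
                                        exclude_molecules = s_mols))),
      "stage 'core_charges'")
  }
  bad <- at; bad$s[1] <- -1
  expect_error(train_full(bad, po, train_config()), "widths must be")
})

test_that("molecule-level splits have floor/ceiling sizes and are seeded", {
  sp <- split_molecules(1:37, train_fraction = 0.8, seed = 5)
  expect_length(sp$train, floor(37 * 0.8))
  expect_length(sp$test, 37 - floor(37 * 0.8))
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- split_molecules(1:37, train_fraction = 0.8, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_molecules(1:37, 0.8, seed = 6)))
})

test_that("the optimizer's best-so-far loss trace is non-increasing", {
  tabs <- train_fix$tabs
  at <- tabs$atoms[tabs$atoms$molecule_id <= 8, ]
  mi <- mlmm:::.table_molecules(at)
  X <- soap_stack(lapply(mi, `[[`, "mol"))
  basis <- ivm_select(X, threshold = 0.05)$selected
  wm <- fit_valence_widths(at, X, basis)
  fit <- suppressWarnings(
    fit_electronegativities(at, X, basis, wm,
                            train_config(adam_iters = 60)))
  best <- cummin(fit$loss_trace)
  expect_true(all(diff(best) <= 0))
  expect_lt(fit$charge_rmse, 0.05)
})
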