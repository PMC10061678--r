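## Four-stage training workflow:
##   1. element core charges        -- per-element means of reference q_core
##   2. valence widths              -- sparse GPR on reference s
##   3. electronegativities + a_QEq -- Adam on the charge MSD through the
##                                     differentiable QEq solve (analytic
##                                     adjoint of the bordered KKT system)
##   4. k_Z + a_Thole               -- least squares on molecular dipolar
##                                     polarizability components
## Stages consume the tabular reference formats written by
## make_reference_tables() (or converted from a real density partitioning).

#' Training configuration
#'
#' @param soap an [soap_config()].
#' @param ivm_threshold IVM posterior-variance threshold for the basis.
#' @param gpr_noise observation-noise variance for the width GPR.
#' @param chi_jitter jitter on the basis Gram matrix used by the
#'   electronegativity GPR interpolation map.
#' @param adam_lr,adam_iters,adam_tol Adam learning rate, iteration cap and
#'   gradient-infinity-norm tolerance for stage 3.
#' @param a_qeq_init,a_thole_init,k_z_init positive initial values for the
#'   scalar physics parameters.
#' @param seed RNG seed recorded in the checkpoint (the workflow itself is
#'   deterministic; the seed also drives any train/test splitting).
#' @param exclude_molecules molecule ids to drop before training (explicit
#'   exclusion list, e.g. for distorted geometries).
#' @param max_basis optional cap on the IVM basis size.
#' @return A list of class `mlmm_train_config`.
#' @export
train_config <- function(soap = soap_config(), ivm_threshold = 0.05,
                         gpr_noise = 1e-8, chi_jitter = 1e-8,
                         adam_lr = 0.01, adam_iters = 1000L, adam_tol = 1e-6,
                         a_qeq_init = 1.2, a_thole_init = 0.5,
                         k_z_init = 0.2, seed = 1L,
                         exclude_molecules = integer(0),
                         max_basis = Inf) {
  stopifnot(ivm_threshold > 0, a_qeq_init > 0, a_thole_init > 0, k_z_init > 0)
  structure(list(soap = soap, ivm_threshold = ivm_threshold,
                 gpr_noise = gpr_noise, chi_jitter = chi_jitter,
                 adam_lr = adam_lr, adam_iters = as.integer(adam_iters),
                 adam_tol = adam_tol, a_qeq_init = a_qeq_init,
                 a_thole_init = a_thole_init, k_z_init = k_z_init,
                 seed = as.integer(seed),
                 exclude_molecules = exclude_molecules,
                 max_basis = max_basis),
            class = "mlmm_train_config")
}

.check_atom_table <- function(records) {
  need <- c("molecule_id", "element", "x", "y", "z", "q_core", "q_val", "s")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(records$s <= 0)) stop("reference widths must be > 0", call. = FALSE)
  invisible(records)
}

#' Stage 1: per-element core charges
#'
#' Arithmetic mean of the reference core charges within each element; errors
#' if any supported element is absent from the table.
#'
#' @param records reference atom table (see [make_reference_tables()]).
#' @param elements elements that must be covered.
#' @return Named numeric vector of core charges, e.
#' @export
fit_core_charges <- function(records, elements = supported_elements()) {
  .check_atom_table(records)
  miss <- setdiff(elements, unique(records$element))
  if (length(miss))
    stop("no reference atoms for element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- tapply(records$q_core, records$element, mean)
  stats::setNames(as.numeric(out[elements]), elements)
}

## molecules + per-molecule row indices from an atom table
.table_molecules <- function(records) {
  ids <- unique(records$molecule_id)
  lapply(ids, function(id) {
    rows <- which(records$molecule_id == id)
    q_tot <- sum(records$q_core[rows] + records$q_val[rows])
    if (abs(q_tot - round(q_tot)) > 1e-6)
      stop(sprintf("molecule %s: reference charges sum to non-integer %.6f",
                   id, q_tot), call. = FALSE)
    list(id = id, rows = rows,
         mol = molecule(records$element[rows],
                        cbind(records$x[rows], records$y[rows],
                              records$z[rows]),
                        total_charge = round(q_tot)))
  })
}

#' Stage 2: sparse GPR for valence widths
#'
#' @param records reference atom table.
#' @param X SOAP feature matrix aligned with the table rows.
#' @param basis inducing-point indices (from [ivm_select()]).
#' @param noise observation-noise variance.
#' @param zeta kernel exponent.
#' @return An `mlmm_sparse_gpr` for the Slater width `s` (Bohr).
#' @export
fit_valence_widths <- function(records, X, basis, noise = 1e-8, zeta = 2) {
  .check_atom_table(records)
  fit_sparse(X, records$s, basis = basis, elements = records$element,
             zeta = zeta, noise = noise)
}

## GPR interpolation map from basis values to all training atoms:
## chi_atoms = K_NM (K_MM + j I)^{-1} chi_basis
.gpr_interp_map <- function(X, basis, zeta, jitter) {
  Knm <- soap_kernel(X, X[basis, , drop = FALSE], zeta)
  Kmm <- Knm[basis, , drop = FALSE]
  fac <- .chol_with_jitter((Kmm + t(Kmm)) / 2, jitter, 1e-4)
  list(W = t(backsolve(fac$chol,
                       backsolve(fac$chol, t(Knm), transpose = TRUE))),
       jitter = fac$jitter)
}

## per-molecule geometry cache for the stage-3 loss
.qeq_train_cache <- function(records, mol_index, s_pred) {
  lapply(mol_index, function(mi) {
    rows <- mi$rows
    pos <- to_bohr(mi$mol$xyz)
    n <- length(rows)
    R <- as.matrix(stats::dist(pos))
    list(rows = rows, n = n, R = R, s = s_pred[rows],
         q_ref = records$q_core[rows] + records$q_val[rows],
         q_tot = mi$mol$total_charge)
  })
}

## loss, gradient wrt per-atom chi and log(a_qeq), and predicted charges
.qeq_loss <- function(cache, chi_atoms, a_qeq, n_total) {
  loss <- 0
  g_chi <- numeric(n_total)
  g_loga <- 0
  q_pred <- numeric(n_total)
  for (cc in cache) {
    n <- cc$n
    sig <- a_qeq * cc$s
    A <- matrix(0, n, n)
    diag(A) <- qeq_hardness(sig)
    if (n > 1) for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      A[i, j] <- A[j, i] <- qeq_pair_interaction(sig[i], sig[j], cc$R[i, j])
    }
    M <- rbind(cbind(A, 1), c(rep(1, n), 0))
    x <- solve(M, c(-chi_atoms[cc$rows], cc$q_tot))
    q <- x[seq_len(n)]
    r <- q - cc$q_ref
    loss <- loss + sum(r^2)
    q_pred[cc$rows] <- q
    # adjoint of the bordered solve: M z = [dL/dq; 0] (M symmetric)
    z <- solve(M, c(2 * r, 0))
    g_chi[cc$rows] <- -z[seq_len(n)]
    # dA/d(log a): diagonal -J; off-diagonal -(2/sqrt(pi)) u exp(-u^2) / R
    dA <- matrix(0, n, n)
    diag(dA) <- -diag(A)
    if (n > 1) for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      gg <- sqrt(2 * (sig[i]^2 + sig[j]^2))
      u <- cc$R[i, j] / gg
      dA[i, j] <- dA[j, i] <- -(2 / sqrt(pi)) * u * exp(-u^2) / cc$R[i, j]
    }
    g_loga <- g_loga - drop(z[seq_len(n)] %*% dA %*% q)
  }
  list(loss = loss / n_total, g_chi = g_chi / n_total,
       g_loga = g_loga / n_total, q_pred = q_pred)
}

#' Stage 3: electronegativities and the QEq width factor
#'
#' Learns one electronegativity per basis environment (training-set values
#' obtained from them by GPR interpolation, as in the published workflow)
#' plus the universal width factor `a_QEq`, by minimizing the mean squared
#' deviation between QEq-predicted and reference total charges. The
#' optimizer is Adam on `(chi_basis, log a_QEq)` with an analytic adjoint
#' gradient through the bordered KKT solve; the basis values are warm-started
#' by the exact ridge least-squares solution at the initial `a_QEq` (charges
#' are linear in chi for fixed `a_QEq`).
#'
#' @param records reference atom table.
#' @param X SOAP feature matrix aligned with the table rows.
#' @param basis inducing-point indices.
#' @param width_model stage-2 `mlmm_sparse_gpr` (predicted widths feed
#'   `sigma = a_QEq * s`).
#' @param config an [train_config()].
#' @return A list with `chi_model` (an `mlmm_sparse_gpr` interpolating the
#'   basis electronegativities), `a_qeq`, `chi_basis`, the Adam `loss_trace`,
#'   final `charge_rmse` (e) and `converged`.
#' @export
fit_electronegativities <- function(records, X, basis, width_model,
                                    config = train_config()) {
  .check_atom_table(records)
  mol_index <- .table_molecules(records)
  s_pred <- predict(width_model, X, elements = records$element)
  if (any(s_pred <= 0))
    stop("width model predicts non-positive widths", call. = FALSE)
  n_total <- nrow(X)
  cache <- .qeq_train_cache(records, mol_index, s_pred)
  interp <- .gpr_interp_map(X, basis, width_model$zeta, config$chi_jitter)
  W <- interp$W
  m <- length(basis)

  ## warm start: charges are linear in chi for fixed a_qeq
  ## (q = -P W chi_b + t per molecule, P the charge block of M^{-1}), so the
  ## basis chi has an exact ridge least-squares solution at any a_qeq.
  ## Profile that solution over log(a_qeq) with a 1-D minimizer, then let
  ## Adam polish the joint parameter vector.
  q_ref_all <- records$q_core + records$q_val
  ridge <- 1e-8
  ls_at <- function(a) {
    G <- matrix(0, n_total, m); tvec <- numeric(n_total)
    for (cc in cache) {
      n <- cc$n
      sig <- a * cc$s
      A <- matrix(0, n, n)
      diag(A) <- qeq_hardness(sig)
      if (n > 1) for (i in seq_len(n - 1)) {
        j <- (i + 1):n
        A[i, j] <- A[j, i] <- qeq_pair_interaction(sig[i], sig[j],
                                                   cc$R[i, j])
      }
      Minv <- solve(rbind(cbind(A, 1), c(rep(1, n), 0)))
      G[cc$rows, ] <- -Minv[seq_len(n), seq_len(n), drop = FALSE] %*%
        W[cc$rows, , drop = FALSE]
      tvec[cc$rows] <- Minv[seq_len(n), n + 1] * cc$q_tot
    }
    chi_b <- drop(solve(crossprod(G) + diag(ridge, m),
                        crossprod(G, q_ref_all - tvec)))
    list(chi_b = chi_b,
         loss = mean((drop(G %*% chi_b) + tvec - q_ref_all)^2))
  }
  prof <- stats::optimize(function(la) ls_at(exp(la))$loss,
                          interval = log(config$a_qeq_init) + c(-1.2, 1.2),
                          tol = 1e-8)
  a0 <- exp(prof$minimum)
  chi_b <- ls_at(a0)$chi_b

  ## Adam polish on (chi_basis, log a_qeq)
  theta <- c(chi_b, log(a0))
  mm_ <- vv_ <- numeric(m + 1)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(0)
  converged <- FALSE
  best <- list(loss = Inf, theta = theta)
  for (it in seq_len(config$adam_iters)) {
    chi_atoms <- drop(W %*% theta[seq_len(m)])
    ev <- .qeq_loss(cache, chi_atoms, exp(theta[m + 1]), n_total)
    g <- c(drop(crossprod(W, ev$g_chi)), ev$g_loga)
    trace <- c(trace, ev$loss)
    if (ev$loss < best$loss) best <- list(loss = ev$loss, theta = theta)
    if (max(abs(g)) < config$adam_tol) { converged <- TRUE; break }
    mm_ <- b1 * mm_ + (1 - b1) * g
    vv_ <- b2 * vv_ + (1 - b2) * g^2
    theta <- theta - config$adam_lr * (mm_ / (1 - b1^it)) /
      (sqrt(vv_ / (1 - b2^it)) + eps)
  }
  if (!converged) {
    theta <- best$theta
    warning("electronegativity fit: gradient tolerance not reached; ",
            "keeping best iterate (loss ", signif(best$loss, 4), ")")
  }
  chi_b <- theta[seq_len(m)]
  a_qeq <- exp(theta[m + 1])
  ev <- .qeq_loss(cache, drop(W %*% chi_b), a_qeq, n_total)

  ## package the chi predictor as a kernel expansion over the basis
  Xb <- X[basis, , drop = FALSE]
  Kmm <- soap_kernel(Xb, Xb, width_model$zeta)
  fac <- .chol_with_jitter((Kmm + t(Kmm)) / 2, interp$jitter, 1e-4)
  wts <- backsolve(fac$chol, backsolve(fac$chol, chi_b, transpose = TRUE))
  attr(Xb, "config_key") <- attr(X, "config_key")
  chi_model <- structure(
    list(basis_features = Xb,
         basis_elements = attr(X, "center_elements")[basis],
         weights = as.numeric(wts), zeta = width_model$zeta,
         noise = 0, jitter = fac$jitter,
         intercepts = stats::setNames(rep(0, length(supported_elements())),
                                      supported_elements())),
    class = "mlmm_sparse_gpr")
  list(chi_model = chi_model, a_qeq = a_qeq, chi_basis = chi_b,
       loss_trace = trace, charge_rmse = sqrt(ev$loss),
       converged = converged)
}

#' Stage 4: polarizability/volume ratios and the Thole damping factor
#'
#' Least-squares fit of the five per-element `k_Z` and the universal
#' `a_Thole` to reference molecular dipolar polarizability tensors,
#' component-wise, through the exact Thole solve with volume-based atomic
#' polarizabilities. Parameters are log-parameterized (never leave the
#' positive domain); geometries that would trip the polarization catastrophe
#' during line search are penalized rather than fatal. With only single-atom
#' molecules `a_Thole` is unidentifiable and is reported at its initial
#' value with a warning.
#'
#' @param records reference atom table.
#' @param polarizabilities reference tensor table (`molecule_id`,
#'   `axx`..`azz` unique components).
#' @param volumes per-atom predicted MBIS volumes aligned with `records`,
#'   Bohr^3.
#' @param config an [train_config()].
#' @return A list with named `k_z`, `a_thole`, the optimizer value
#'   `tensor_mse` (Bohr^6) and `identifiable`.
#' @export
fit_polarizability_params <- function(records, polarizabilities, volumes,
                                      config = train_config()) {
  .check_atom_table(records)
  mol_index <- .table_molecules(records)
  ids <- vapply(mol_index, `[[`, numeric(1), "id")
  prow <- match(ids, polarizabilities$molecule_id)
  if (anyNA(prow))
    stop("polarizability table is missing molecule(s): ",
         paste(ids[is.na(prow)], collapse = ", "), call. = FALSE)
  ref <- as.matrix(polarizabilities[prow, c("axx", "axy", "axz",
                                            "ayy", "ayz", "azz")])
  elements <- supported_elements()
  el_present <- intersect(elements, unique(records$element))
  multi <- any(vapply(mol_index, function(mi) length(mi$rows) > 1, TRUE))
  if (any(volumes <= 0))
    stop("non-positive predicted volumes; check the width/charge models",
         call. = FALSE)

  tensor_components <- function(k_z, a_thole) {
    out <- matrix(0, length(mol_index), 6)
    for (mi in seq_along(mol_index)) {
      rows <- mol_index[[mi]]$rows
      a <- volumes_to_alphas(volumes[rows], records$element[rows], k_z)
      am <- molecular_polarizability(
        thole_system(a, to_bohr(mol_index[[mi]]$mol$xyz), a_thole))
      out[mi, ] <- c(am[1, 1], am[1, 2], am[1, 3], am[2, 2], am[2, 3],
                     am[3, 3])
    }
    out
  }
  # off-diagonal components appear twice in the full tensor MSD
  wcomp <- c(1, 2, 2, 1, 2, 1)
  obj <- function(theta) {
    k_z <- stats::setNames(exp(theta[seq_along(el_present)]), el_present)
    a_thole <- exp(theta[length(el_present) + 1])
    pred <- tryCatch(tensor_components(k_z, a_thole),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e8)   # polarization catastrophe: penalize
    sum(sweep((pred - ref)^2, 2, wcomp, "*")) / (9 * nrow(ref))
  }
  theta0 <- c(rep(log(config$k_z_init), length(el_present)),
              log(config$a_thole_init))
  # log-parameterized, box-bounded: keeps k_Z and a_thole positive and stops
  # the optimizer from wandering along flat directions (a_thole is nearly
  # unidentifiable when all atom pairs are far separated)
  opt <- stats::optim(theta0, obj, method = "L-BFGS-B",
                      lower = -8, upper = 6,
                      control = list(maxit = 500, factr = 1e4))
  k_fit <- stats::setNames(exp(opt$par[seq_along(el_present)]), el_present)
  a_fit <- exp(opt$par[length(el_present) + 1])
  if (!multi) {
    warning("no multi-atom molecules: a_thole is unidentifiable; ",
            "reporting its initial value")
    a_fit <- config$a_thole_init
  }
  k_z <- stats::setNames(rep(NA_real_, length(elements)), elements)
  k_z[el_present] <- k_fit
  list(k_z = k_z, a_thole = a_fit, tensor_mse = opt$value,
       identifiable = multi)
}

#' Run the full four-stage training workflow
#'
#' Executes core charges, valence widths, electronegativities and
#' polarizability parameters in order and assembles the final embedding
#' model. Deterministic given the configuration seed.
#'
#' @param atom_table reference atom table (`molecule_id`, `element`, `x`,
#'   `y`, `z`, `q_core`, `q_val`, `s`).
#' @param pol_table reference polarizability table (`molecule_id`,
#'   `axx`..`azz`).
#' @param config an [train_config()].
#' @return An object of class `mlmm_embedding_model`.
#' @export
train_full <- function(atom_table, pol_table, config = train_config()) {
  .check_atom_table(atom_table)
  if (length(config$exclude_molecules)) {
    atom_table <- atom_table[!(atom_table$molecule_id %in%
                                 config$exclude_molecules), , drop = FALSE]
    pol_table <- pol_table[!(pol_table$molecule_id %in%
                               config$exclude_molecules), , drop = FALSE]
  }
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("training stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  q_core <- stage("core_charges", fit_core_charges(atom_table))
  mol_index <- .table_molecules(atom_table)
  X <- stage("descriptors", {
    rowsX <- lapply(mol_index, function(mi)
      soap_matrix(mi$mol, config$soap))
    ord <- order(unlist(lapply(mol_index, `[[`, "rows")))
    Xall <- do.call(rbind, rowsX)[ord, , drop = FALSE]
    attr(Xall, "center_elements") <- atom_table$element
    attr(Xall, "config_key") <- config$soap$key
    Xall
  })
  ivm <- stage("basis_selection",
               ivm_select(X, zeta = 2, threshold = config$ivm_threshold,
                          max_basis = min(config$max_basis, nrow(X))))
  width_model <- stage("valence_widths",
                       fit_valence_widths(atom_table, X, ivm$selected,
                                          noise = config$gpr_noise))
  chi_fit <- stage("electronegativities",
                   fit_electronegativities(atom_table, X, ivm$selected,
                                           width_model, config))
  s_pred <- predict(width_model, X, elements = atom_table$element)
  chi_pred <- predict(chi_fit$chi_model, X, elements = atom_table$element)
  q_pred <- .predict_charges_tab(atom_table, mol_index, chi_pred,
                                 chi_fit$a_qeq, s_pred)
  q_val_pred <- q_pred - q_core[atom_table$element]
  volumes <- stage("volumes", atomic_volume(q_val_pred, s_pred))
  pol_fit <- stage("polarizability",
                   fit_polarizability_params(atom_table, pol_table, volumes,
                                             config))
  structure(list(q_core = q_core, width_model = width_model,
                 chi_model = chi_fit$chi_model, a_qeq = chi_fit$a_qeq,
                 k_z = pol_fit$k_z, a_thole = pol_fit$a_thole,
                 soap = config$soap, basis = ivm$selected,
                 seed = config$seed,
                 diagnostics = list(
                   n_basis = length(ivm$selected),
                   charge_rmse = chi_fit$charge_rmse,
                   chi_converged = chi_fit$converged,
                   tensor_mse = pol_fit$tensor_mse,
                   loss_trace = chi_fit$loss_trace)),
            class = "mlmm_embedding_model")
}

## QEq charges for all rows of an atom table under given chi, a_qeq, s
.predict_charges_tab <- function(records, mol_index, chi, a_qeq, s) {
  q <- numeric(nrow(records))
  for (mi in mol_index) {
    rows <- mi$rows
    sys <- qeq_system(chi[rows], a_qeq * s[rows], to_bohr(mi$mol$xyz),
                      q_tot = mi$mol$total_charge)
    q[rows] <- solve_qeq(sys)$charges
  }
  q
}

#' @export
print.mlmm_embedding_model <- function(x, ...) {
  cat("<mlmm_embedding_model>\n")
  cat(sprintf("  basis environments : %d\n", x$diagnostics$n_basis))
  cat(sprintf("  a_QEq              : %.4f\n", x$a_qeq))
  cat(sprintf("  a_Thole            : %.4f\n", x$a_thole))
  cat(sprintf("  k_Z                : %s\n",
              paste(sprintf("%s=%.3f", names(x$k_z), x$k_z),
                    collapse = " ")))
  cat(sprintf("  training charge RMSE: %.5f e\n",
              x$diagnostics$charge_rmse))
  invisible(x)
}

#' Seeded molecule-level train/test split
#'
#' @param molecule_ids vector of molecule ids.
#' @param train_fraction fraction assigned to the training set.
#' @param seed RNG seed.
#' @return A list with `train` and `test` id vectors (sizes
#'   `floor`/`ceiling` of the fraction).
#' @export
split_molecules <- function(molecule_ids, train_fraction = 0.8, seed = 1L) {
  ids <- unique(molecule_ids)
  set.seed(seed)
  n_train <- floor(length(ids) * train_fraction)
  tr <- sort(sample(ids, n_train))
  list(train = tr, test = sort(setdiff(ids, tr)))
}
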