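## End-to-end embedding prediction: from a molecule, an MM point-charge mesh
## and a trained model to the decomposed embedding energy
##
##   E_emb = E_static + E_induced_interaction + E_pol
##
## with E_static = sum_i q_i V_static(r_i) over MM charges,
## E_induced_interaction = sum_i q_i V_ind(r_i), and E_pol the cost of
## creating the induced dipoles. The alternative `induction = "variational"`
## reports the minimized induction objective (-1/2 sum mu.E) instead of the
## two-term sum; the two coincide for a single polarizable site and differ
## by the dipole-dipole coupling otherwise.

#' Predict the embedding energy of a molecule in a point-charge mesh
#'
#' Pipeline: SOAP features -> per-atom valence width and electronegativity
#' (sparse GPR) -> element core charges -> QEq charges
#' (`sigma = a_QEq * s`) -> static Slater-density energy; MBIS volumes ->
#' volume-based polarizabilities -> Thole induced dipoles under the MM
#' fields -> induced interaction + polarization cost. An empty mesh returns
#' exactly zero for every energy component.
#'
#' @param mol an [molecule()] (all elements must be covered by the model).
#' @param mm an [mm_charges()] mesh.
#' @param model an `mlmm_embedding_model` from [train_full()] or
#'   [read_model()].
#' @param induction `"paper"` (default: charge-induced-potential interaction
#'   plus polarization cost) or `"variational"` (minimized induction
#'   objective).
#' @return An object of class `mlmm_embedding_result` with energies in
#'   kcal/mol (`e_static`, `e_induced_interaction`, `e_pol`, `e_total`),
#'   per-atom `charges` (e), `dipoles` (e Bohr) and `alphas` (Bohr^3).
#' @export
predict_embedding <- function(mol, mm, model,
                              induction = c("paper", "variational")) {
  induction <- match.arg(induction)
  miss <- setdiff(unique(mol$elements), names(model$q_core))
  if (length(miss))
    stop("model does not cover element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(model$k_z[unique(mol$elements)])))
    stop("model has no k_Z for element(s): ",
         paste(unique(mol$elements)[is.na(model$k_z[unique(mol$elements)])],
               collapse = ", "), call. = FALSE)
  X <- soap_matrix(mol, model$soap)
  s_pred <- predict(model$width_model, X, elements = mol$elements)
  if (any(s_pred <= 0))
    stop("predicted non-positive valence width; molecule outside the ",
         "model's domain", call. = FALSE)
  chi_pred <- predict(model$chi_model, X, elements = mol$elements)
  q_core <- unname(model$q_core[mol$elements])
  sol <- solve_qeq(qeq_system(chi_pred, model$a_qeq * s_pred,
                              to_bohr(mol$xyz), q_tot = mol$total_charge))
  q <- sol$charges
  q_val <- q - q_core
  dens <- static_density_model(mol, q_core, q_val, s_pred)
  alphas <- volumes_to_alphas(atomic_volume(q_val, s_pred), mol$elements,
                              model$k_z[!is.na(model$k_z)])
  n <- n_atoms(mol)
  if (n_charges(mm) == 0) {
    e_static_h <- e_ind_h <- e_pol_h <- 0
    mu <- matrix(0, n, 3)
  } else {
    e_static_h <- static_embedding_energy(dens, mol, mm)
    tsys <- thole_system(alphas, to_bohr(mol$xyz), model$a_thole)
    fields <- mm_fields(mol, mm)
    dip <- solve_dipoles(tsys, fields)
    mu <- dip$mu
    e_pol_h <- polarization_cost(tsys, dip)
    if (induction == "paper") {
      vind <- induced_potential(tsys, dip, to_bohr(mm$positions))
      e_ind_h <- sum(mm$charges * vind)
    } else {
      e_ind_h <- -0.5 * sum(mu * fields) - e_pol_h  # so ind + pol = -1/2 mu.E
    }
  }
  structure(list(
    e_static = hartree_to_kcalmol(e_static_h),
    e_induced_interaction = hartree_to_kcalmol(e_ind_h),
    e_pol = hartree_to_kcalmol(e_pol_h),
    e_total = hartree_to_kcalmol(e_static_h + e_ind_h + e_pol_h),
    charges = q, dipoles = mu, alphas = alphas,
    widths = s_pred, chi = chi_pred, induction = induction),
    class = "mlmm_embedding_result")
}

#' @export
print.mlmm_embedding_result <- function(x, ...) {
  cat("<mlmm_embedding_result> (kcal/mol)\n")
  cat(sprintf("  static      : %12.4f\n", x$e_static))
  cat(sprintf("  induced int.: %12.4f\n", x$e_induced_interaction))
  cat(sprintf("  polarization: %12.4f\n", x$e_pol))
  cat(sprintf("  total       : %12.4f\n", x$e_total))
  invisible(x)
}

#' Evaluate embedding predictions against reference energies
#'
#' Computes the RMSE of the predicted embedding energy over a set of
#' snapshots, both raw and after removing the mean (systematic) error --
#' the convention used when embedding models are compared against explicit
#' QM/MM references. Component RMSEs are reported when reference static /
#' induced values are provided.
#'
#' @param snapshots a list; each element a list with `mol`, `mm`,
#'   `reference` (kcal/mol) and optionally `reference_static`,
#'   `reference_induced`.
#' @param model an `mlmm_embedding_model`.
#' @param induction passed to [predict_embedding()].
#' @return A list of class `mlmm_evaluation` with per-snapshot predictions,
#'   `rmse`, `rmse_after_mean_removal` and, where references allow,
#'   `rmse_static`, `rmse_induced` (all mean-removed component RMSEs are
#'   also included).
#' @export
evaluate_embedding <- function(snapshots, model,
                               induction = c("paper", "variational")) {
  stopifnot(length(snapshots) >= 2)
  induction <- match.arg(induction)
  preds <- lapply(snapshots, function(sn)
    predict_embedding(sn$mol, sn$mm, model, induction = induction))
  pred_tot <- vapply(preds, `[[`, 0.0, "e_total")
  ref_tot <- vapply(snapshots, function(sn) as.numeric(sn$reference), 0.0)
  if (any(!is.finite(ref_tot)))
    stop("missing or non-finite reference energies", call. = FALSE)
  rmse <- function(x) sqrt(mean(x^2))
  d <- pred_tot - ref_tot
  out <- list(predicted = pred_tot, reference = ref_tot,
              rmse = rmse(d), rmse_after_mean_removal = rmse(d - mean(d)))
  ref_st <- vapply(snapshots, function(sn)
    if (is.null(sn$reference_static)) NA_real_ else
      as.numeric(sn$reference_static), 0.0)
  if (!anyNA(ref_st)) {
    ds <- vapply(preds, `[[`, 0.0, "e_static") - ref_st
    out$rmse_static <- rmse(ds)
    out$rmse_static_after_mean_removal <- rmse(ds - mean(ds))
  }
  ref_in <- vapply(snapshots, function(sn)
    if (is.null(sn$reference_induced)) NA_real_ else
      as.numeric(sn$reference_induced), 0.0)
  if (!anyNA(ref_in)) {
    di <- vapply(preds, function(p)
      p$e_induced_interaction + p$e_pol, 0.0) - ref_in
    out$rmse_induced <- rmse(di)
    out$rmse_induced_after_mean_removal <- rmse(di - mean(di))
  }
  structure(out, class = "mlmm_evaluation")
}

#' @export
print.mlmm_evaluation <- function(x, ...) {
  cat("<mlmm_evaluation> (kcal/mol)\n")
  cat(sprintf("  RMSE               : %.4f\n", x$rmse))
  cat(sprintf("  RMSE (mean removed): %.4f\n", x$rmse_after_mean_removal))
  if (!is.null(x$rmse_static))
    cat(sprintf("  static RMSE        : %.4f\n", x$rmse_static))
  if (!is.null(x$rmse_induced))
    cat(sprintf("  induced RMSE       : %.4f\n", x$rmse_induced))
  invisible(x)
}
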