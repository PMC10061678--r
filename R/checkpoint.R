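## Model checkpoints: one JSON document holding every artifact needed to
## reproduce predictions -- descriptor configuration, basis features, GPR
## weights and intercepts, and the physics parameters. The schema is
## versioned; readers refuse unknown versions.

CHECKPOINT_SCHEMA <- 1L

.gpr_to_list <- function(m) {
  list(basis_features = unclass(m$basis_features),
       basis_elements = m$basis_elements,
       weights = m$weights, zeta = m$zeta, noise = m$noise,
       jitter = m$jitter, intercepts = as.list(m$intercepts))
}

.gpr_from_list <- function(l, config_key) {
  Xb <- l$basis_features
  if (!is.matrix(Xb)) Xb <- do.call(rbind, lapply(Xb, as.numeric))
  attr(Xb, "config_key") <- config_key
  structure(list(basis_features = Xb,
                 basis_elements = as.character(unlist(l$basis_elements)),
                 weights = as.numeric(unlist(l$weights)),
                 zeta = as.numeric(l$zeta), noise = as.numeric(l$noise),
                 jitter = as.numeric(l$jitter),
                 intercepts = unlist(l$intercepts)),
            class = "mlmm_sparse_gpr")
}

#' Write an embedding model checkpoint
#'
#' Serializes the model (descriptor configuration, GPR bases and weights,
#' physics parameters, seeds) to a single self-describing JSON file at full
#' numeric precision.
#'
#' @param model an `mlmm_embedding_model`.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  doc <- list(
    schema = CHECKPOINT_SCHEMA,
    package = "mlmm",
    soap = unclass(model$soap),
    q_core = as.list(model$q_core),
    width_model = .gpr_to_list(model$width_model),
    chi_model = .gpr_to_list(model$chi_model),
    a_qeq = model$a_qeq,
    k_z = as.list(model$k_z),
    a_thole = model$a_thole,
    seed = model$seed,
    diagnostics = model$diagnostics[c("n_basis", "charge_rmse",
                                      "chi_converged", "tensor_mse")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read an embedding model checkpoint
#'
#' @param path path to a JSON checkpoint written by [write_model()].
#' @return An `mlmm_embedding_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(doc$schema), CHECKPOINT_SCHEMA))
    stop("unsupported checkpoint schema version: ", doc$schema, call. = FALSE)
  soap <- doc$soap
  cfg <- soap_config(r_cut = soap$r_cut, n_max = soap$n_max,
                     l_max = soap$l_max, sigma_atom = soap$sigma_atom,
                     species = soap$species, n_quad = soap$n_quad)
  structure(list(q_core = unlist(doc$q_core),
                 width_model = .gpr_from_list(doc$width_model, cfg$key),
                 chi_model = .gpr_from_list(doc$chi_model, cfg$key),
                 a_qeq = doc$a_qeq,
                 k_z = unlist(doc$k_z),
                 a_thole = doc$a_thole,
                 soap = cfg, seed = doc$seed,
                 diagnostics = doc$diagnostics),
            class = "mlmm_embedding_model")
}
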