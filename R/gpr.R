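## Sparse Gaussian-process regression on SOAP kernels.
##
## The mean function is a per-element intercept (element mean of the
## targets); the GP learns deviations from it. Sparsity follows the
## projected-process construction with an inducing basis chosen by the
## Informative Vector Machine: greedily pick the environment with the largest
## posterior variance until the largest variance drops below a threshold.

#' Informative-Vector-Machine basis selection
#'
#' Greedy maximum-posterior-variance selection over a set of environments
#' under the polynomial SOAP kernel. With unit-normalized features every
#' prior variance is 1; ties are broken by lowest index, so the selection is
#' deterministic. Selection stops when the maximum posterior variance falls
#' below `threshold`, or reports saturation when duplicates exhaust the
#' attainable variance first.
#'
#' @param X feature matrix from [soap_matrix()] (rows = environments).
#' @param zeta kernel exponent.
#' @param threshold variance threshold in (0, 1] (the published model uses
#'   0.05).
#' @param max_basis optional cap on the basis size.
#' @param jitter numerical jitter on the basis Gram diagonal.
#' @return A list of class `mlmm_ivm` with `selected` (ordered indices),
#'   `variance_trace` (max posterior variance after each pick) and
#'   `saturated` (logical).
#' @export
ivm_select <- function(X, zeta = 2, threshold = 0.05, max_basis = nrow(X),
                       jitter = 1e-8) {
  X <- rbind(X)
  n <- nrow(X)
  stopifnot(n >= 1, threshold > 0)
  K <- soap_kernel(X, X, zeta)
  v <- rep(1, n)                       # normalized kernel: prior variance 1
  Q <- matrix(0, n, 0)
  selected <- integer(0)
  trace <- numeric(0)
  saturated <- FALSE
  floor_v <- max(100 * jitter, 1e-6)
  repeat {
    if (length(selected) >= max_basis) break
    s <- which.max(v)                  # first index on ties
    if (length(selected) > 0 && v[s] < threshold) break
    if (length(selected) > 0 && v[s] < floor_v) { saturated <- TRUE; break }
    ldiag <- sqrt(v[s] + jitter)
    qnew <- (K[, s] - if (ncol(Q)) Q %*% Q[s, ] else 0) / ldiag
    Q <- cbind(Q, as.numeric(qnew))
    v <- pmax(v - as.numeric(qnew)^2, 0)
    selected <- c(selected, s)
    trace <- c(trace, max(v))
    if (max(v) < threshold) break
  }
  if (max(v) >= threshold && !saturated && length(selected) >= max_basis &&
      max_basis < n)
    warning("IVM stopped at max_basis before reaching the variance threshold")
  structure(list(selected = selected, variance_trace = trace,
                 saturated = saturated),
            class = "mlmm_ivm")
}

.chol_with_jitter <- function(M, jitter0 = 1e-8, jitter_max = 1e-4) {
  j <- jitter0
  repeat {
    ch <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = j))
    if (j >= jitter_max)
      stop("Gram matrix not factorizable even at jitter ", jitter_max,
           call. = FALSE)
    j <- j * 10
  }
}

#' Fit a sparse (projected-process) GPR model
#'
#' Minimizes the regularized projected-process objective
#' \deqn{\|K_{NM} w + D\beta - y\|^2 + \sigma_n^2\, w^T K_{MM} w}
#' where `D` is the per-element indicator matrix, so the per-element
#' intercepts \eqn{\beta} (the explicit mean function) are fitted jointly
#' with the kernel weights, universal-kriging style. In the noise-free
#' full-basis limit this interpolates the targets; for constant targets the
#' intercepts absorb everything and the weights vanish.
#'
#' @param X training feature matrix ([soap_matrix()]).
#' @param y numeric targets, one per row of `X`.
#' @param elements per-environment centre elements (defaults to the
#'   `center_elements` attribute of `X`).
#' @param basis integer indices of the inducing environments (e.g.
#'   `ivm_select(X)$selected`).
#' @param zeta kernel exponent.
#' @param noise observation-noise variance (>= 0).
#' @return An object of class `mlmm_sparse_gpr` holding the basis features,
#'   weights, per-element intercepts and kernel settings.
#' @export
fit_sparse <- function(X, y, basis, elements = attr(X, "center_elements"),
                       zeta = 2, noise = 1e-8) {
  force(elements)
  key <- attr(X, "config_key")
  X <- rbind(X)
  attr(X, "config_key") <- key
  stopifnot(length(y) == nrow(X), length(basis) >= 1, noise >= 0)
  if (is.null(elements)) stop("centre elements required", call. = FALSE)
  stopifnot(length(elements) == nrow(X))
  if (any(!is.finite(y))) stop("targets must be finite", call. = FALSE)
  Xb <- X[basis, , drop = FALSE]
  Knm <- t(soap_kernel(X, X, zeta)[basis, , drop = FALSE])  # n x m
  Kmm <- Knm[basis, , drop = FALSE]
  lev <- sort(unique(elements))
  D <- outer(elements, lev, `==`) + 0                       # n x p indicators
  m <- length(basis); p <- length(lev)
  # augmented least squares (QR, not normal equations, for conditioning):
  # rows = data, sqrt(noise) * chol(Kmm) on the weights, and a tiny ridge
  fac <- .chol_with_jitter((Kmm + t(Kmm)) / 2)
  ridge <- 1e-10
  A <- rbind(cbind(Knm, D),
             cbind(sqrt(noise) * fac$chol, matrix(0, m, p)),
             sqrt(ridge) * diag(m + p))
  sol <- qr.coef(qr(A), c(y, numeric(2 * m + p)))
  attr(Xb, "config_key") <- attr(X, "config_key")
  structure(list(basis_features = Xb,
                 basis_elements = elements[basis],
                 weights = as.numeric(sol[seq_len(m)]), zeta = zeta,
                 noise = noise, jitter = fac$jitter,
                 intercepts = stats::setNames(as.numeric(sol[m + seq_len(p)]),
                                              lev)),
            class = "mlmm_sparse_gpr")
}

#' Predict with a sparse GPR model
#'
#' Kernel expansion over the basis plus the per-element intercept.
#'
#' @param object an `mlmm_sparse_gpr` model.
#' @param X query feature matrix (same descriptor configuration as training).
#' @param elements query centre elements (defaults to the matrix attribute).
#' @param ... unused.
#' @return Numeric predictions, one per query row (empty input gives an
#'   empty vector).
#' @export
predict.mlmm_sparse_gpr <- function(object, X,
                                    elements = attr(X, "center_elements"),
                                    ...) {
  if (is.null(X) || (is.matrix(X) && nrow(X) == 0)) return(numeric(0))
  force(elements)
  key <- attr(X, "config_key")
  X <- rbind(X)
  attr(X, "config_key") <- key
  if (is.null(elements)) stop("centre elements required", call. = FALSE)
  miss <- setdiff(unique(elements), names(object$intercepts))
  if (length(miss))
    stop("no intercept for element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  Kxm <- soap_kernel(X, object$basis_features, object$zeta)
  drop(Kxm %*% object$weights) + unname(object$intercepts[elements])
}
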