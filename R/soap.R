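## SOAP power-spectrum descriptors of atomic environments.
##
## The neighbour density around a centre atom is a sum of Gaussians of width
## sigma_atom placed on every atom (centre included) within r_cut, each
## weighted by a smooth cosine cutoff. The density is expanded in
## species-resolved channels on an orthonormalized radial basis of Gaussians
## times real spherical harmonics up to l_max; the rotationally invariant
## power spectrum
##
##   p^{Z1 Z2}_{n1 n2 l} = pi sqrt(8 / (2l + 1)) sum_m c^{Z1}_{n1 l m} c^{Z2}_{n2 l m}
##
## is flattened (species pairs Z1 <= Z2, off-diagonal blocks scaled by
## sqrt(2) so the dot product equals the full sum) and L2-normalized. The
## expansion coefficients use the standard Gaussian-on-a-sphere projection
##
##   c_{nlm} += w_j 4 pi Y_lm(rhat_j) int g_n(r) r^2 e^{-a(r^2+d^2)} i_l(2 a r d) dr
##
## with a = 1/(2 sigma_atom^2) and i_l the modified spherical Bessel
## function, evaluated through exponentially scaled besselI for stability.

#' SOAP descriptor configuration
#'
#' Defaults follow the embedding model's published setup: 3 Angstrom cutoff,
#' four radial and four angular channels, ordered species H, C, N, O, S. The
#' radial basis (Gaussians centred on an even radial grid, Lowdin
#' orthonormalized) and the atom-density width of 0.5 Angstrom are this
#' implementation's documented defaults and are recorded in every model
#' checkpoint so trained models are self-describing.
#'
#' @param r_cut environment cutoff radius, Angstrom.
#' @param n_max number of radial basis functions.
#' @param l_max maximum spherical-harmonic degree.
#' @param sigma_atom width of the neighbour-density Gaussians, Angstrom.
#' @param species ordered element list resolved in the density channels.
#' @param n_quad radial quadrature nodes (Gauss-Legendre on `[0, r_cut]`).
#' @return An object of class `mlmm_soap_config`.
#' @export
soap_config <- function(r_cut = 3.0, n_max = 4L, l_max = 4L,
                        sigma_atom = 0.5, species = supported_elements(),
                        n_quad = 64L) {
  stopifnot(r_cut > 0, n_max >= 1, l_max >= 1, sigma_atom > 0,
            length(species) >= 1, n_quad >= 16)
  atomic_number(species)
  cfg <- structure(list(r_cut = r_cut, n_max = as.integer(n_max),
                        l_max = as.integer(l_max), sigma_atom = sigma_atom,
                        species = as.character(species),
                        n_quad = as.integer(n_quad),
                        cutoff = "cosine", radial_basis = "gaussian-lowdin",
                        version = 1L),
                   class = "mlmm_soap_config")
  cfg$key <- paste(r_cut, n_max, l_max, sigma_atom,
                   paste(species, collapse = ""), n_quad, sep = "|")
  cfg
}

## smooth cosine cutoff; 1 at r = 0, 0 at r >= r_cut
.f_cut <- function(r, r_cut) ifelse(r < r_cut, 0.5 * (cos(pi * r / r_cut) + 1), 0)

## Gauss-Legendre nodes/weights on [0, r_cut] plus the orthonormalized radial
## basis evaluated on the nodes (columns = basis functions)
.radial_basis <- function(cfg) {
  gl <- pracma::gaussLegendre(cfg$n_quad, 0, cfg$r_cut)
  centers <- (seq_len(cfg$n_max) - 0.5) * cfg$r_cut / cfg$n_max
  width <- cfg$r_cut / cfg$n_max
  B <- sapply(centers, function(c0) exp(-(gl$x - c0)^2 / (2 * width^2)))
  S <- t(B) %*% (gl$w * gl$x^2 * B)           # overlap with r^2 measure
  es <- eigen(S, symmetric = TRUE)
  S_inv_half <- es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-14)),
                                    cfg$n_max) %*% t(es$vectors)
  list(x = gl$x, w = gl$w, B = B %*% S_inv_half)
}

## real spherical harmonics Y_lm for one unit vector, rows l = 0..l_max,
## list of numeric vectors m = -l..l (Condon-Shortley absorbed)
.real_sph_harm <- function(l_max, v) {
  x <- v[3]                                    # cos(theta)
  phi <- atan2(v[2], v[1])
  # associated Legendre P_l^m(x), m >= 0, via standard recurrences
  P <- matrix(0, l_max + 1, l_max + 1)         # [l+1, m+1]
  somx2 <- sqrt(max(0, 1 - x^2))
  for (m in 0:l_max) {
    pmm <- 1
    if (m > 0) pmm <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
    P[m + 1, m + 1] <- pmm
    if (m < l_max) {
      pmmp1 <- x * (2 * m + 1) * pmm
      P[m + 2, m + 1] <- pmmp1
      if (m + 2 <= l_max) for (l in (m + 2):l_max) {
        pll <- (x * (2 * l - 1) * pmmp1 - (l + m - 1) * pmm) / (l - m)
        pmm <- pmmp1; pmmp1 <- pll
        P[l + 1, m + 1] <- pll
      }
    }
  }
  out <- vector("list", l_max + 1)
  for (l in 0:l_max) {
    y <- numeric(2 * l + 1)                    # index m + l + 1
    y[l + 1] <- sqrt((2 * l + 1) / (4 * pi)) * P[l + 1, 1]
    if (l > 0) for (m in 1:l) {
      nlm <- sqrt((2 * l + 1) / (2 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      y[l + m + 1] <- nlm * P[l + 1, m + 1] * cos(m * phi)
      y[l - m + 1] <- nlm * P[l + 1, m + 1] * sin(m * phi)
    }
    out[[l + 1]] <- y
  }
  out
}

## h_l(r, d) = exp(-a (r^2 + d^2)) i_l(2 a r d) for the quadrature grid r
## (vector) and one neighbour distance d; numerically stable at small/zero x
.radial_kernel <- function(r, d, a, l) {
  x <- 2 * a * r * d
  out <- numeric(length(r))
  big <- x > 1e-6
  if (any(big)) {
    iscaled <- besselI(x[big], l + 0.5, expon.scaled = TRUE)
    out[big] <- sqrt(pi / (2 * x[big])) * iscaled * exp(-a * (r[big] - d)^2)
  }
  if (any(!big)) {
    xs <- x[!big]
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    il <- xs^l / dfact * (1 + xs^2 / (2 * (2 * l + 3)))
    out[!big] <- il * exp(-a * (r[!big]^2 + d^2))
  }
  out
}

## expansion coefficients for one centre: array [species, n, l, m-index]
.soap_coeffs <- function(mol, center, cfg, rad) {
  a <- 1 / (2 * cfg$sigma_atom^2)
  n_sp <- length(cfg$species)
  cmat <- array(0, c(n_sp, cfg$n_max, cfg$l_max + 1, 2 * cfg$l_max + 1))
  dvec <- sweep(mol$xyz, 2, mol$xyz[center, ], "-")
  dist <- sqrt(rowSums(dvec^2))
  nb <- which(dist < cfg$r_cut)
  for (j in nb) {
    zi <- match(mol$elements[j], cfg$species)
    if (is.na(zi)) next
    wj <- .f_cut(dist[j], cfg$r_cut)
    if (j == center) {
      # centre atom: direction undefined, only l = 0 survives
      h0 <- exp(-a * rad$x^2)
      Inl <- colSums(rad$w * rad$x^2 * h0 * rad$B)
      cmat[zi, , 1, 1] <- cmat[zi, , 1, 1] +
        wj * 4 * pi * (1 / sqrt(4 * pi)) * Inl
      next
    }
    y <- .real_sph_harm(cfg$l_max, dvec[j, ] / dist[j])
    for (l in 0:cfg$l_max) {
      hl <- .radial_kernel(rad$x, dist[j], a, l)
      Inl <- colSums(rad$w * rad$x^2 * hl * rad$B)     # length n_max
      for (mi in seq_len(2 * l + 1))
        cmat[zi, , l + 1, mi] <- cmat[zi, , l + 1, mi] +
          wj * 4 * pi * y[[l + 1]][mi] * Inl
    }
  }
  cmat
}

## flatten the power spectrum of a coefficient array to the canonical order
.power_spectrum <- function(cmat, cfg) {
  n_sp <- dim(cmat)[1]; n_max <- dim(cmat)[2]; l_max <- dim(cmat)[3] - 1
  out <- numeric(0)
  for (z1 in seq_len(n_sp)) for (z2 in z1:n_sp) {
    sfac_sp <- if (z1 == z2) 1 else sqrt(2)
    for (l in 0:l_max) {
      pref <- pi * sqrt(8 / (2 * l + 1))
      mi <- seq_len(2 * l + 1)
      C1 <- matrix(cmat[z1, , l + 1, mi], n_max)       # n_max x (2l+1)
      C2 <- matrix(cmat[z2, , l + 1, mi], n_max)
      Pl <- pref * C1 %*% t(C2)                        # n1 x n2 block
      if (z1 == z2) {
        v <- Pl[upper.tri(Pl, diag = TRUE)]
        scale <- matrix(sqrt(2), n_max, n_max); diag(scale) <- 1
        v <- v * scale[upper.tri(scale, diag = TRUE)]
      } else {
        v <- sfac_sp * as.numeric(Pl)
      }
      out <- c(out, v)
    }
  }
  out
}

#' SOAP feature vector of one atomic environment
#'
#' Rotation-, translation- and permutation-invariant, L2-normalized power
#' spectrum of the smeared neighbour density around atom `center`. An
#' isolated atom yields its self-contribution-only vector; atoms at or beyond
#' `r_cut` have exactly zero influence.
#'
#' @param mol an [molecule()].
#' @param center centre-atom index.
#' @param config an [soap_config()].
#' @return Numeric feature vector with attributes `center_element` and
#'   `config_key`.
#' @export
soap_features <- function(mol, center, config = soap_config()) {
  stopifnot(center >= 1, center <= n_atoms(mol))
  X <- soap_matrix(mol, config, centers = center)
  v <- X[1, ]
  attr(v, "center_element") <- attr(X, "center_elements")[1]
  attr(v, "config_key") <- attr(X, "config_key")
  v
}

#' SOAP features for many centres at once
#'
#' @param mol an [molecule()].
#' @param config an [soap_config()].
#' @param centers integer vector of centre indices (default: all atoms).
#' @return Numeric matrix, one row per centre, with attributes
#'   `center_elements` and `config_key`.
#' @export
soap_matrix <- function(mol, config = soap_config(),
                        centers = seq_len(n_atoms(mol))) {
  rad <- .radial_basis(config)
  rows <- lapply(centers, function(ci) {
    p <- .power_spectrum(.soap_coeffs(mol, ci, config, rad), config)
    nrm <- sqrt(sum(p^2))
    if (nrm < 1e-300) stop("degenerate (all-zero) SOAP vector", call. = FALSE)
    p / nrm
  })
  X <- do.call(rbind, rows)
  attr(X, "center_elements") <- mol$elements[centers]
  attr(X, "config_key") <- config$key
  X
}

#' Polynomial SOAP kernel
#'
#' \eqn{k(a, b) = (a \cdot b)^\zeta} on L2-normalized feature vectors (dot
#' products clipped at zero), so \eqn{k(a, a) = 1}. Refuses to compare
#' features computed under different descriptor configurations.
#'
#' @param A,B feature matrices from [soap_matrix()] (rows = environments).
#' @param zeta polynomial exponent (default 2).
#' @return The kernel matrix `nrow(A)` x `nrow(B)`.
#' @export
soap_kernel <- function(A, B = A, zeta = 2) {
  A <- rbind(A); B <- rbind(B)
  ka <- attr(A, "config_key"); kb <- attr(B, "config_key")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb))
    stop("SOAP features computed with different configurations", call. = FALSE)
  if (ncol(A) != ncol(B))
    stop("feature length mismatch", call. = FALSE)
  pmax(A %*% t(B), 0)^zeta
}
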