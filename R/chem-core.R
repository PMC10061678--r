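#' @keywords internal
"_PACKAGE"

## Unit system: all physics is done in Hartree atomic units (Bohr, Hartree, e).
## File I/O and user-facing geometry are in Angstrom and e; reported energies
## are kcal/mol.

#' Physical constants and unit conversions
#'
#' CODATA-2018 Bohr radius and the conventional Hartree-to-kcal/mol factor.
#' Round trips through these conversions are exact to machine precision.
#'
#' @format Named numeric constants.
#' @name units
NULL

BOHR_ANGSTROM <- 0.529177210903   # 1 Bohr in Angstrom
HARTREE_KCALMOL <- 627.509474     # 1 Hartree in kcal/mol

#' Convert lengths between Angstrom and Bohr
#'
#' @param x numeric vector/matrix of lengths.
#' @return The converted lengths (same shape as `x`).
#' @examples
#' to_bohr(0.529177210903)   # 1
#' to_angstrom(to_bohr(1.5)) # 1.5
#' @export
to_bohr <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x / BOHR_ANGSTROM
}

#' @rdname to_bohr
#' @export
to_angstrom <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * BOHR_ANGSTROM
}

#' @rdname to_bohr
#' @export
hartree_to_kcalmol <- function(x) x * HARTREE_KCALMOL

#' @rdname to_bohr
#' @export
kcalmol_to_hartree <- function(x) x / HARTREE_KCALMOL

## Closed element set: the embedding model is parameterized for neutral
## ground-state organic compounds built from these five elements only.
ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "S"),
  number = c(1L, 6L, 7L, 8L, 16L),
  stringsAsFactors = FALSE
)

#' Supported chemical elements
#'
#' The model covers H, C, N, O and S. Other symbols are rejected everywhere.
#'
#' @param symbols character vector of element symbols.
#' @return `atomic_number()` returns the integer atomic numbers;
#'   `supported_elements()` the symbol vector.
#' @export
supported_elements <- function() ELEMENTS$symbol

#' @rdname supported_elements
#' @export
atomic_number <- function(symbols) {
  idx <- match(symbols, ELEMENTS$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(ELEMENTS$symbol, collapse = ", "), ")",
         call. = FALSE)
  }
  ELEMENTS$number[idx]
}

#' Construct a QM molecule
#'
#' A molecule is an ordered list of atoms (element symbol + Cartesian position
#' in Angstrom) plus an integer total charge. Positions must be finite and no
#' two atoms may lie closer than `clash_dist`.
#'
#' @param elements character vector of element symbols (H, C, N, O, S).
#' @param xyz numeric n x 3 matrix of positions, Angstrom.
#' @param total_charge integer total molecular charge, e.
#' @param clash_dist minimum allowed interatomic distance, Angstrom.
#' @return An object of class `mlmm_molecule` with fields `elements`, `xyz`,
#'   `total_charge`.
#' @examples
#' water <- molecule(c("O", "H", "H"),
#'                   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' @export
molecule <- function(elements, xyz, total_charge = 0L, clash_dist = 0.3) {
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || ncol(xyz) != 3)
    stop("xyz must be an n x 3 matrix", call. = FALSE)
  n <- length(elements)
  if (n < 1) stop("a molecule needs at least one atom", call. = FALSE)
  if (nrow(xyz) != n)
    stop("elements and xyz disagree in length", call. = FALSE)
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  atomic_number(elements)  # validates the element gate
  if (!isTRUE(all.equal(total_charge, round(total_charge))))
    stop("total_charge must be integral", call. = FALSE)
  if (n > 1) {
    d <- stats::dist(xyz)
    if (min(d) < clash_dist)
      stop(sprintf("atoms closer than clash distance (%.3g < %.3g Angstrom)",
                   min(d), clash_dist), call. = FALSE)
  }
  structure(list(elements = as.character(elements),
                 xyz = unname(xyz),
                 total_charge = as.integer(round(total_charge))),
            class = "mlmm_molecule")
}

#' @export
print.mlmm_molecule <- function(x, ...) {
  cat(sprintf("<mlmm_molecule> %d atoms (%s), total charge %+d e\n",
              length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "", collapse = " "),
              x$total_charge))
  invisible(x)
}

#' Number of atoms
#' @param mol an `mlmm_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Construct an MM point-charge mesh
#'
#' @param positions numeric n x 3 matrix, Angstrom. May have zero rows.
#' @param charges numeric vector of point charges, e (zero charges retained).
#' @return An object of class `mlmm_mm_charges` with fields `positions`,
#'   `charges`.
#' @export
mm_charges <- function(positions, charges) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  charges <- as.numeric(charges)
  if (nrow(positions) != length(charges))
    stop("positions and charges disagree in length", call. = FALSE)
  if (!all(is.finite(positions)) || !all(is.finite(charges)))
    stop("non-finite point-charge data", call. = FALSE)
  structure(list(positions = unname(positions), charges = charges),
            class = "mlmm_mm_charges")
}

#' @export
print.mlmm_mm_charges <- function(x, ...) {
  cat(sprintf("<mlmm_mm_charges> %d charges, net %+.4f e\n",
              length(x$charges), sum(x$charges)))
  invisible(x)
}

#' @rdname mm_charges
#' @param x an `mlmm_mm_charges` object.
#' @export
n_charges <- function(x) length(x$charges)

.parse_num <- function(tok, path, lineno, what) {
  v <- suppressWarnings(as.numeric(tok))
  if (anyNA(v))
    stop(sprintf("%s: line %d: non-numeric %s '%s'",
                 path, lineno, what, tok[which(is.na(v))[1]]), call. = FALSE)
  v
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then `El x y z` rows in
#' Angstrom. Unsupported elements and malformed lines raise errors naming the
#' offending line.
#'
#' @param path file path.
#' @param total_charge integer total charge to attach (XYZ carries none).
#' @return An [molecule()] object with atoms in file order.
#' @export
read_xyz <- function(path, total_charge = 0L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop(path, ": empty file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop(path, ": line 1: malformed atom count '", lines[1], "'", call. = FALSE)
  if (length(lines) < n + 2)
    stop(sprintf("%s: count line says %d atoms but only %d atom rows present",
                 path, n, max(0L, length(lines) - 2L)), call. = FALSE)
  el <- character(n); xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lineno <- i + 2L
    tok <- strsplit(trimws(lines[lineno]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop(sprintf("%s: line %d: expected 'El x y z', got '%s'",
                   path, lineno, lines[lineno]), call. = FALSE)
    el[i] <- tok[1]
    xyz[i, ] <- .parse_num(tok[2:4], path, lineno, "coordinate")
  }
  molecule(el, xyz, total_charge = total_charge)
}

#' Write a molecule to an XYZ file
#'
#' @param mol an `mlmm_molecule`.
#' @param path output file path.
#' @param comment comment-line text.
#' @export
write_xyz <- function(mol, path, comment = "") {
  rows <- sprintf("%-2s %18.12f %18.12f %18.12f",
                  mol$elements, mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3])
  writeLines(c(as.character(n_atoms(mol)), comment, rows), path)
  invisible(path)
}

#' Read an MM point-charge file
#'
#' Count-prefixed text, one `q x y z` row per charge (charge in e, position in
#' Angstrom) -- the external-charge dialect used by common QM engines. A count
#' of zero yields an empty mesh.
#'
#' @param path file path.
#' @return An [mm_charges()] object, rows in file order.
#' @export
read_point_charges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop(path, ": empty file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0)
    stop(path, ": line 1: malformed charge count '", lines[1], "'", call. = FALSE)
  body <- lines[-1]
  body_n <- sum(nzchar(trimws(body)))
  if (body_n != n)
    stop(sprintf("%s: count line says %d charges but %d rows present",
                 path, n, body_n), call. = FALSE)
  q <- numeric(n); pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) != 4)
      stop(sprintf("%s: line %d: expected 'q x y z', got %d fields",
                   path, i + 1L, length(tok)), call. = FALSE)
    v <- .parse_num(tok, path, i + 1L, "field")
    q[i] <- v[1]; pos[i, ] <- v[2:4]
  }
  mm_charges(pos, q)
}

#' Write an MM point-charge file
#'
#' @param mm an `mlmm_mm_charges` object.
#' @param path output file path.
#' @export
write_point_charges <- function(mm, path) {
  rows <- sprintf("%18.12f %18.12f %18.12f %18.12f",
                  mm$charges, mm$positions[, 1], mm$positions[, 2],
                  mm$positions[, 3])
  writeLines(c(as.character(n_charges(mm)), rows), path)
  invisible(path)
}
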