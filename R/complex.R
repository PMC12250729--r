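#' @keywords internal
"_PACKAGE"

## Canonical atom-table columns. Every atom system handed to an energy
## backend is a data.frame with (at least) these columns; coordinates in
## Angstrom, charges in elementary charge units, LJ well depth in kcal/mol,
## rmin2 = r_min/2 in Angstrom.
.atom_cols <- c("serial", "name", "elem", "x", "y", "z",
                "charge", "eps", "rmin2",
                "chain", "resno", "resid", "ligand", "role")

.empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), elem = character(),
             x = numeric(), y = numeric(), z = numeric(),
             charge = numeric(), eps = numeric(), rmin2 = numeric(),
             chain = character(), resno = integer(), resid = character(),
             ligand = logical(), role = character(),
             stringsAsFactors = FALSE)
}

.check_atoms <- function(atoms, what = "atom table") {
  miss <- setdiff(.atom_cols, names(atoms))
  if (length(miss) > 0L)
    stop(what, " is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) > 0L) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop(what, " contains non-finite coordinates", call. = FALSE)
    if (any(!nzchar(atoms$elem)))
      stop(what, " contains atoms with empty element symbols", call. = FALSE)
    if (any(atoms$eps < 0, na.rm = TRUE))
      stop(what, " contains negative Lennard-Jones well depths", call. = FALSE)
  }
  invisible(atoms)
}

#' Construct a protein-ligand complex
#'
#' Bundles an atom table into a validated complex object: a polymer of
#' sequence-ordered residues plus exactly one non-polymer group flagged as
#' the ligand.  This is the container every downstream stage
#' (fragmentation, pocket selection, energy evaluation) operates on.
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `x`, `y`,
#'   `z`, `charge`, `eps`, `rmin2`, `chain`, `resno`, `resid`, `ligand`,
#'   `role`.  Coordinates in Angstrom, charges in e, `eps` (LJ well depth)
#'   in kcal/mol, `rmin2` (half the LJ minimum-energy distance) in Angstrom.
#' @param source optional provenance string (file path).
#'
#' @return An object of class `mfcc_complex`.
#' @export
mfcc_complex <- function(atoms, source = NA_character_) {
  .check_atoms(atoms, "complex atom table")
  if (sum(atoms$ligand) == 0L)
    stop("complex has no ligand group", call. = FALSE)
  lig_keys <- unique(.res_key(atoms[atoms$ligand, ]))
  if (length(lig_keys) != 1L)
    stop("complex must contain exactly one ligand group, found ",
         length(lig_keys), call. = FALSE)
  pol <- atoms[!atoms$ligand, ]
  if (nrow(pol) == 0L)
    stop("complex has no polymer residues", call. = FALSE)
  ## duplicate (chain, resno) with conflicting residue names is a format error
  grp <- unique(pol[, c("chain", "resno", "resid")])
  if (anyDuplicated(grp[, c("chain", "resno")]) > 0L)
    stop("duplicate (chain, seq) identifiers with conflicting residue names",
         call. = FALSE)
  ## polymer stored sequence-ordered
  atoms <- rbind(pol[order(pol$chain, pol$resno), ], atoms[atoms$ligand, ])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "mfcc_complex")
}

.res_key <- function(atoms) paste(atoms$chain, atoms$resno, sep = ":")

#' @export
print.mfcc_complex <- function(x, ...) {
  pol <- x$atoms[!x$atoms$ligand, ]
  lig <- x$atoms[x$atoms$ligand, ]
  cat(sprintf(
    "mfcc_complex: %d polymer residues (%d atoms), ligand %s (%d atoms)\n",
    length(unique(.res_key(pol))), nrow(pol), lig$resid[1], nrow(lig)))
  invisible(x)
}

#' Polymer residue table of a complex
#'
#' @param complex an [mfcc_complex()].
#' @return data.frame with one row per polymer residue (`chain`, `resno`,
#'   `resid`, `n_atoms`) in sequence order.
#' @export
residue_table <- function(complex) {
  stopifnot(inherits(complex, "mfcc_complex"))
  pol <- complex$atoms[!complex$atoms$ligand, ]
  key <- .res_key(pol)
  idx <- !duplicated(key)
  out <- pol[idx, c("chain", "resno", "resid")]
  out$n_atoms <- as.integer(table(key)[key[idx]])
  rownames(out) <- NULL
  out
}

#' Ligand atoms of a complex
#' @param complex an [mfcc_complex()].
#' @return data.frame of the ligand group's atoms.
#' @export
ligand_atoms <- function(complex) {
  stopifnot(inherits(complex, "mfcc_complex"))
  complex$atoms[complex$atoms$ligand, , drop = FALSE]
}

#' Atoms of one polymer residue
#' @param complex an [mfcc_complex()].
#' @param chain,resno residue identifier.
#' @return data.frame of that residue's atoms.
#' @export
residue_atoms <- function(complex, chain, resno) {
  stopifnot(inherits(complex, "mfcc_complex"))
  a <- complex$atoms
  out <- a[!a$ligand & a$chain == chain & a$resno == resno, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no polymer residue ", chain, ":", resno, " in complex",
         call. = FALSE)
  out
}
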