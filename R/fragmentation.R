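## Conjugate-cap fragmentation: cleave the peptide bonds around a target
## residue, cap it with its two neighbouring residues, hydrogen-terminate
## every cleaved bond, and assemble the ligand-residue interaction energy
## from the four capped systems
##   E_I(L-Ri) = E(L + Ci-1 Ri Ci+1) - E(Ci-1 Ri Ci+1)
##             - E(L + Ci-1 Ci+1)    + E(Ci-1 Ci+1)
## so that all cap-only contributions cancel.

#' Capping specification
#'
#' Geometry rules for the hydrogens that terminate cleaved peptide bonds.
#' Each added hydrogen sits on the exact former-bond unit vector at a
#' standard bond length; nothing is re-optimized.
#'
#' @param ch_bond_length C-H bond length in Angstrom (hydrogen replacing a
#'   bond that left a carbonyl carbon dangling).
#' @param nh_bond_length N-H bond length in Angstrom (hydrogen replacing a
#'   bond that left an amide nitrogen dangling).
#' @param max_peptide_bond maximum C(i)-N(i+1) distance in Angstrom for two
#'   consecutive residues to count as bonded; a larger gap is treated as a
#'   chain break (that side becomes a terminus).
#' @return An object of class `cap_spec`.
#' @export
cap_spec <- function(ch_bond_length = 1.090, nh_bond_length = 1.010,
                     max_peptide_bond = 2.0) {
  stopifnot(ch_bond_length > 0.5, ch_bond_length < 1.5,
            nh_bond_length > 0.5, nh_bond_length < 1.5)
  structure(list(ch = ch_bond_length, nh = nh_bond_length,
                 max_bond = max_peptide_bond), class = "cap_spec")
}

.bb_atom <- function(res, name, what) {
  i <- which(res$name == name)
  if (length(i) != 1L)
    stop("missing backbone atom ", name, " in residue ",
         res$chain[1], ":", res$resno[1], " (", what, ")", call. = FALSE)
  res[i, , drop = FALSE]
}

.dist3 <- function(a, b) sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)

## hydrogen on `parent` pointing toward `toward` at `len` Angstrom;
## zero charge and LJ depth so added caps stay energetically silent under
## the classical backend unless explicitly parameterized
.cap_hydrogen <- function(parent, toward, len, role, serial) {
  v <- c(toward$x - parent$x, toward$y - parent$y, toward$z - parent$z)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9)
    stop("degenerate bond vector while placing cap hydrogen", call. = FALSE)
  u <- v / nv
  data.frame(serial = as.integer(serial), name = "Hcap", elem = "H",
             x = parent$x + len * u[1], y = parent$y + len * u[2],
             z = parent$z + len * u[3],
             charge = 0, eps = 0, rmin2 = 0,
             chain = parent$chain, resno = parent$resno,
             resid = parent$resid, ligand = FALSE, role = role,
             stringsAsFactors = FALSE)
}

#' Build the four capped systems for one residue
#'
#' Cleaves the two peptide bonds flanking the target residue and returns
#' the four atom systems whose energies combine into the ligand-residue
#' interaction energy: ligand + capped residue, capped residue,
#' ligand + concap, and concap.  The caps are the entire neighbouring
#' residues i-1 and i+1 at their source geometry (side chains included).
#' The concap is those two caps with a junction hydrogen replacing each
#' bond that went to the target residue; the caps' outer ends (bonds to
#' residues i-2 / i+2, where they exist) are hydrogen-terminated
#' identically in all systems containing them.  All source atoms keep
#' their coordinates unchanged.
#'
#' Terminal residues get a cap only on the side where a neighbour exists;
#' a sequence gap or a C(i)-N(i+1) distance above
#' `spec$max_peptide_bond` is treated as a chain break (warning logged).
#'
#' @param complex a parameterized [mfcc_complex()].
#' @param chain,resno target residue identifier (must be a polymer
#'   residue, not the ligand).
#' @param spec a [cap_spec()].
#' @return An object of class `fragment_quartet` with elements
#'   `residue_key`, the four atom systems `sys_l_cap_r_cap`,
#'   `sys_cap_r_cap`, `sys_l_concap`, `sys_concap`, and the serial vectors
#'   `junction_h` and `outer_h`.
#' @export
build_quartet <- function(complex, chain, resno, spec = cap_spec()) {
  stopifnot(inherits(complex, "mfcc_complex"), inherits(spec, "cap_spec"))
  at <- complex$atoms
  lig <- at[at$ligand, , drop = FALSE]
  if (any(lig$chain == chain & lig$resno == resno))
    stop("target ", chain, ":", resno,
         " is the ligand group; fragmentation applies to polymer residues",
         call. = FALSE)
  pol <- at[!at$ligand & at$chain == chain, , drop = FALSE]
  resnos <- sort(unique(pol$resno))
  pos <- match(resno, resnos)
  if (is.na(pos))
    stop("no polymer residue ", chain, ":", resno, " in complex",
         call. = FALSE)
  res_at <- function(p) {
    if (p < 1L || p > length(resnos)) return(NULL)
    pol[pol$resno == resnos[p], , drop = FALSE]
  }
  R <- res_at(pos)

  ## neighbour exists if present in sequence and peptide-bonded
  bonded_prev <- function(p) {           # residue p-1 -> p bond
    a <- res_at(p - 1L); b <- res_at(p)
    if (is.null(a) || is.null(b)) return(FALSE)
    if (!("C" %in% a$name) || !("N" %in% b$name)) return(FALSE)
    ok <- .dist3(.bb_atom(a, "C", "bond check"),
                 .bb_atom(b, "N", "bond check")) <= spec$max_bond
    if (!ok)
      warning("chain break between ", chain, ":", resnos[p - 1L], " and ",
              chain, ":", resnos[p], "; treating as terminus", call. = FALSE)
    ok
  }
  has_prev <- pos > 1L && bonded_prev(pos)
  has_next <- pos < length(resnos) && bonded_prev(pos + 1L)
  if (!has_prev && !has_next)
    stop("residue ", chain, ":", resno,
         " has no bonded neighbour on either side; cannot fragment",
         call. = FALSE)

  capA <- if (has_prev) res_at(pos - 1L) else NULL
  capB <- if (has_next) res_at(pos + 1L) else NULL
  next_serial <- max(at$serial) + 1L
  new_h <- list(); outer_ids <- integer(0); junction_ids <- integer(0)
  add_h <- function(parent, toward, len, role) {
    h <- .cap_hydrogen(parent, toward, len, role, next_serial)
    next_serial <<- next_serial + 1L
    new_h[[length(new_h) + 1L]] <<- h
    h$serial
  }

  ## outer terminations: only where an i-2 / i+2 bond was actually cleaved
  if (has_prev && pos - 1L > 1L && bonded_prev(pos - 1L)) {
    prev2 <- res_at(pos - 2L)
    outer_ids <- c(outer_ids,
                   add_h(.bb_atom(capA, "N", "outer cap"),
                         .bb_atom(prev2, "C", "outer cap"),
                         spec$nh, "outer"))
  }
  if (has_next && pos + 1L < length(resnos) && bonded_prev(pos + 2L)) {
    next2 <- res_at(pos + 2L)
    outer_ids <- c(outer_ids,
                   add_h(.bb_atom(capB, "C", "outer cap"),
                         .bb_atom(next2, "N", "outer cap"),
                         spec$ch, "outer"))
  }
  ## junction hydrogens: replace the two bonds that went to the target
  if (has_prev)
    junction_ids <- c(junction_ids,
                      add_h(.bb_atom(capA, "C", "junction"),
                            .bb_atom(R, "N", "junction"),
                            spec$ch, "junction"))
  if (has_next)
    junction_ids <- c(junction_ids,
                      add_h(.bb_atom(capB, "N", "junction"),
                            .bb_atom(R, "C", "junction"),
                            spec$nh, "junction"))

  hdf <- do.call(rbind, new_h)
  outer_h_df <- hdf[hdf$serial %in% outer_ids, , drop = FALSE]
  junction_h_df <- hdf[hdf$serial %in% junction_ids, , drop = FALSE]

  bindrows <- function(...) {
    parts <- Filter(function(p) !is.null(p) && nrow(p) > 0L, list(...))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  sys_cap_r_cap <- bindrows(capA, R, capB, outer_h_df)
  sys_concap <- bindrows(capA, capB, outer_h_df, junction_h_df)
  structure(list(
    residue_key = list(chain = chain, resno = resno, resid = R$resid[1]),
    sys_l_cap_r_cap = bindrows(lig, sys_cap_r_cap),
    sys_cap_r_cap = sys_cap_r_cap,
    sys_l_concap = bindrows(lig, sys_concap),
    sys_concap = sys_concap,
    junction_h = junction_ids,
    outer_h = outer_ids),
    class = "fragment_quartet")
}

#' @export
print.fragment_quartet <- function(x, ...) {
  cat(sprintf(
    "fragment_quartet for %s:%d (%s)\n  systems: %d / %d / %d / %d atoms; %d junction H, %d outer H\n",
    x$residue_key$chain, x$residue_key$resno, x$residue_key$resid,
    nrow(x$sys_l_cap_r_cap), nrow(x$sys_cap_r_cap),
    nrow(x$sys_l_concap), nrow(x$sys_concap),
    length(x$junction_h), length(x$outer_h)))
  invisible(x)
}

#' Four-fragment ligand-residue interaction energy
#'
#' Evaluates the backend on the quartet's four systems and combines them
#' as `E(L+cap R cap) - E(cap R cap) - E(L+concap) + E(concap)`.
#' Negative values are attractive.
#'
#' @param quartet a [build_quartet()] result.
#' @param backend an [energy_backend()].
#' @param dielectric relative dielectric constant passed to the backend.
#' @return Interaction energy in kcal/mol.
#' @export
mfcc_interaction_energy <- function(quartet, backend, dielectric) {
  stopifnot(inherits(quartet, "fragment_quartet"),
            inherits(backend, "energy_backend"))
  ev <- function(sys, label) {
    e <- tryCatch(backend$evaluate(sys, dielectric), error = function(err)
      stop(sprintf("backend '%s' failed on system '%s': %s", backend$label,
                   label, conditionMessage(err)), call. = FALSE))
    if (!is.finite(e))
      stop(sprintf("backend '%s' returned a non-finite energy for '%s'",
                   backend$label, label), call. = FALSE)
    e
  }
  ev(quartet$sys_l_cap_r_cap, "ligand+cap-R-cap") -
    ev(quartet$sys_cap_r_cap, "cap-R-cap") -
    ev(quartet$sys_l_concap, "ligand+concap") +
    ev(quartet$sys_concap, "concap")
}

#' Export the four quartet systems as XYZ files
#'
#' @param quartet a [build_quartet()] result.
#' @param dir output directory (created if needed).
#' @return Character vector of the four paths, invisibly.
#' @export
write_quartet_xyz <- function(quartet, dir) {
  stopifnot(inherits(quartet, "fragment_quartet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  key <- sprintf("%s_%d_%s", quartet$residue_key$chain,
                 quartet$residue_key$resno, quartet$residue_key$resid)
  roles <- c("L-capRcap", "capRcap", "L-concap", "concap")
  systems <- list(quartet$sys_l_cap_r_cap, quartet$sys_cap_r_cap,
                  quartet$sys_l_concap, quartet$sys_concap)
  paths <- file.path(dir, sprintf("%s_%s.xyz", key, roles))
  for (i in seq_along(paths))
    write_xyz(systems[[i]], paths[i],
              comment = sprintf("residue %s system %s", key, roles[i]))
  invisible(paths)
}
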