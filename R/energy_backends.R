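## Energy backends: the evaluation contract behind the four fragment
## energies.  The built-in classical backend is a nonbonded
## Coulomb + Lennard-Jones sum; a plain-text emitter/parser adapts
## external quantum-chemistry codes to the same contract.

#' Classical nonbonded energy of an atom system
#'
#' Sums, over all unordered atom pairs,
#' \deqn{E = \sum_{i<j} \frac{332.0637\, q_i q_j}{\varepsilon\, r_{ij}}
#'   + \epsilon_{ij}\left[\left(\frac{r_{min,ij}}{r_{ij}}\right)^{12}
#'   - 2 \left(\frac{r_{min,ij}}{r_{ij}}\right)^{6}\right]}
#' with Lorentz-Berthelot-style combination
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}} and
#' \eqn{r_{min,ij} = r_{min,i}/2 + r_{min,j}/2}.  The uniform dielectric
#' divides the Coulomb term only, standing in for a continuum solvent.
#' No bonded terms and no 1-2/1-3 exclusions are applied: the
#' four-fragment energy difference evaluates identical-geometry
#' subsystems, so every intra-fragment term cancels exactly and
#' exclusions are unnecessary.
#'
#' @param system atom data.frame (see [mfcc_complex()] columns).
#' @param dielectric relative dielectric constant (> 0).
#' @param exclude_junction if `TRUE`, atoms with `role == "junction"`
#'   (cap hydrogens replacing the cleaved bonds to the target residue)
#'   contribute nothing.
#' @return Energy in kcal/mol; negative is attractive.
#' @export
classical_energy <- function(system, dielectric, exclude_junction = FALSE) {
  stopifnot(is.numeric(dielectric), length(dielectric) == 1L, dielectric > 0)
  .check_atoms(system, "energy system")
  if (exclude_junction)
    system <- system[system$role != "junction", , drop = FALSE]
  n <- nrow(system)
  if (n < 2L) return(0)
  D <- as.matrix(stats::dist(cbind(system$x, system$y, system$z)))
  ut <- upper.tri(D)
  if (any(D[ut] < 0.1)) {
    ij <- which(D < 0.1 & ut, arr.ind = TRUE)[1L, ]
    stop(sprintf("atomic clash (r < 0.1 A) between atoms %s:%s and %s:%s",
                 system$serial[ij[1]], system$name[ij[1]],
                 system$serial[ij[2]], system$name[ij[2]]), call. = FALSE)
  }
  qq <- tcrossprod(system$charge)
  coul <- COULOMB_KCAL * sum(qq[ut] / D[ut]) / dielectric
  eij <- sqrt(tcrossprod(system$eps))
  rmin <- outer(system$rmin2, system$rmin2, `+`)
  sr6 <- (rmin[ut] / D[ut])^6
  lj <- sum(eij[ut] * (sr6^2 - 2 * sr6))
  coul + lj
}

#' Brute-force cross-group pair energy
#'
#' Double loop over all (a, b) atom pairs with the same pair formula as
#' [classical_energy()].  This is the oracle for the cap-cancellation
#' property: for any strictly pairwise-additive backend the four-fragment
#' assembly reduces, by term cancellation, to
#' `pairsum(L, Ri) - pairsum(L, junction hydrogens)`.
#'
#' @param system_a,system_b disjoint atom data.frames.
#' @param dielectric relative dielectric constant.
#' @return Energy in kcal/mol.
#' @export
pairsum <- function(system_a, system_b, dielectric) {
  stopifnot(is.numeric(dielectric), length(dielectric) == 1L, dielectric > 0)
  if (is.null(nrow(system_a)) || is.null(nrow(system_b)))
    stop("pairsum expects atom data.frames", call. = FALSE)
  if (nrow(system_a) == 0L || nrow(system_b) == 0L) return(0)
  .check_atoms(system_a, "pairsum system A")
  .check_atoms(system_b, "pairsum system B")
  ka <- paste(system_a$x, system_a$y, system_a$z)
  kb <- paste(system_b$x, system_b$y, system_b$z)
  if (length(intersect(ka, kb)) > 0L)
    stop("pairsum systems overlap (shared atom positions)", call. = FALSE)
  dx <- outer(system_a$x, system_b$x, `-`)
  dy <- outer(system_a$y, system_b$y, `-`)
  dz <- outer(system_a$z, system_b$z, `-`)
  R <- sqrt(dx^2 + dy^2 + dz^2)
  qq <- outer(system_a$charge, system_b$charge)
  eij <- sqrt(outer(system_a$eps, system_b$eps))
  rmin <- outer(system_a$rmin2, system_b$rmin2, `+`)
  sr6 <- (rmin / R)^6
  sum(COULOMB_KCAL * qq / R) / dielectric + sum(eij * (sr6^2 - 2 * sr6))
}

#' Construct an energy backend
#'
#' A backend is the contract behind the four fragment energies: a
#' deterministic function mapping (atom system, dielectric) to a scalar
#' kcal/mol energy, plus a label.  [classical_backend()] wraps
#' [classical_energy()]; external quantum codes are adapted via
#' [emit_qm_input()] / [parse_qm_energy()].
#'
#' @param evaluate function(system, dielectric) -> numeric scalar.
#' @param label short backend name.
#' @return An object of class `energy_backend`.
#' @export
energy_backend <- function(evaluate, label) {
  stopifnot(is.function(evaluate), is.character(label))
  structure(list(evaluate = evaluate, label = label),
            class = "energy_backend")
}

#' @rdname energy_backend
#' @param exclude_junction passed through to [classical_energy()]; with
#'   `TRUE` the junction cap hydrogens are ghosts, which makes the
#'   four-fragment assembly equal the direct ligand-residue pair energy to
#'   machine precision.
#' @export
classical_backend <- function(exclude_junction = FALSE) {
  energy_backend(
    function(system, dielectric)
      classical_energy(system, dielectric, exclude_junction = exclude_junction),
    label = if (exclude_junction) "classical/junction-ghost" else "classical")
}

#' @export
print.energy_backend <- function(x, ...) {
  cat("energy_backend:", x$label, "\n")
  invisible(x)
}

#' Specify a single-point quantum job
#'
#' Labels and settings written into emitted input files.  Defaults mirror
#' a dispersion-corrected GGA single point with a polarizable continuum:
#' B97D/6-311+G(d,p) with CPCM at the requested dielectric.
#'
#' @param method,basis,solvent_model text labels for the route line.
#' @param dielectric continuum dielectric constant (> 0).
#' @param net_charge integer net charge in e, or `NULL` to derive it from
#'   the summed partial charges at emission time.
#' @param multiplicity spin multiplicity (>= 1).
#' @return An object of class `qm_job_spec`.
#' @export
qm_job_spec <- function(method = "B97D", basis = "6-311+G(d,p)",
                        solvent_model = "CPCM", dielectric = 10,
                        net_charge = NULL, multiplicity = 1L) {
  stopifnot(dielectric > 0, multiplicity >= 1)
  structure(list(method = method, basis = basis,
                 solvent_model = solvent_model, dielectric = dielectric,
                 net_charge = net_charge,
                 multiplicity = as.integer(multiplicity)),
            class = "qm_job_spec")
}

#' Emit a plain-text single-point input for an external quantum code
#'
#' Writes a generic route/title/charge-multiplicity/coordinates job file.
#' When `spec$net_charge` is `NULL` the net charge defaults to the summed
#' partial charges rounded to the nearest integer; a sum more than 0.3 e
#' away from any integer raises an error so the caller must decide.
#'
#' @param system non-empty atom data.frame.
#' @param spec a [qm_job_spec()].
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
emit_qm_input <- function(system, spec, path, title = "fragbind single point") {
  stopifnot(inherits(spec, "qm_job_spec"))
  if (is.null(nrow(system)) || nrow(system) == 0L)
    stop("cannot emit a quantum job for an empty system", call. = FALSE)
  net <- spec$net_charge
  if (is.null(net)) {
    s <- sum(system$charge)
    if (abs(s - round(s)) > 0.3)
      stop(sprintf(paste0("summed partial charge %+.4f e is more than 0.3 e",
                          " from an integer; set net_charge explicitly"), s),
           call. = FALSE)
    net <- as.integer(round(s))
  }
  lines <- c(
    sprintf("! SP %s %s %s(eps=%g)", spec$method, spec$basis,
            spec$solvent_model, spec$dielectric),
    "",
    gsub("[\r\n]", " ", title),
    "",
    sprintf("%d %d", net, spec$multiplicity),
    sprintf("%-2s %14.8f %14.8f %14.8f",
            system$elem, system$x, system$y, system$z),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Parse a final energy from a quantum-code output file
#'
#' Scans for lines matching `pattern` (first capture group = energy in
#' Hartree) and converts the value to kcal/mol.  With several matches the
#' last one is used and a message is logged.
#'
#' @param path output-file path.
#' @param pattern regular expression with one capture group holding the
#'   Hartree value.
#' @return Energy in kcal/mol.
#' @export
parse_qm_energy <- function(path,
                            pattern = "ENERGY\\s*=\\s*(-?[0-9]*\\.?[0-9]+([eEdD][+-]?[0-9]+)?)") {
  lines <- readLines(path, warn = FALSE)
  m <- regmatches(lines, regexec(pattern, lines))
  vals <- vapply(m, function(g) if (length(g) >= 2L) g[2] else NA_character_,
                 character(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("no energy line matching '", pattern, "' in ", path, call. = FALSE)
  if (length(vals) > 1L)
    message("parse_qm_energy: ", length(vals),
            " energy lines found, using the last")
  as.numeric(gsub("[dD]", "e", vals[length(vals)])) * HARTREE_KCAL
}
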