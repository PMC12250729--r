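## Binding-pocket analysis: distance-shell residue selection, the
## incremental-radius convergence scan of the total interaction energy,
## and per-residue energy profiles across dielectric constants.

#' Minimum ligand-residue distances
#'
#' For every polymer residue, the minimum Euclidean distance over all
#' (ligand atom, residue atom) pairs, hydrogens included.
#'
#' @param complex an [mfcc_complex()].
#' @return data.frame `chain`, `resno`, `resid`, `min_dist` (Angstrom) in
#'   sequence order.
#' @export
residue_min_distances <- function(complex) {
  stopifnot(inherits(complex, "mfcc_complex"))
  lig <- ligand_atoms(complex)
  pol <- complex$atoms[!complex$atoms$ligand, , drop = FALSE]
  dx <- outer(lig$x, pol$x, `-`)
  dy <- outer(lig$y, pol$y, `-`)
  dz <- outer(lig$z, pol$z, `-`)
  dmin_atom <- apply(sqrt(dx^2 + dy^2 + dz^2), 2L, min)
  key <- .res_key(pol)
  out <- residue_table(complex)[, c("chain", "resno", "resid")]
  out$min_dist <- as.numeric(tapply(dmin_atom, key, min)[.res_key(out)])
  out
}

#' Residues within a distance shell of the ligand
#'
#' A residue belongs to the shell of radius `r` iff its minimum
#' atom-to-atom distance to the ligand is `<= r`.  Shells are nested by
#' construction; an empty shell is allowed.
#'
#' @param complex an [mfcc_complex()].
#' @param radius shell radius in Angstrom (> 0).
#' @return data.frame of the member residues with their `min_dist`.
#' @export
residues_within <- function(complex, radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  md <- residue_min_distances(complex)
  md[md$min_dist <= radius, , drop = FALSE]
}

## convergence rule: smallest successor radius r' with
## |T(r') - T(r)| / |T(r)| < tol simultaneously at every dielectric;
## comparisons against a zero total are skipped (and logged)
.converged_radius <- function(totals, radii, tolerance) {
  stopifnot(is.matrix(totals), nrow(totals) == length(radii))
  for (k in seq_len(nrow(totals))[-1L]) {
    prev <- totals[k - 1L, ]
    cur <- totals[k, ]
    if (any(!is.finite(prev)) || any(!is.finite(cur))) next
    if (any(prev == 0)) {
      message(sprintf(
        "convergence: zero total at r = %g for some dielectric; comparison skipped",
        radii[k - 1L]))
      next
    }
    if (all(abs(cur - prev) / abs(prev) < tolerance))
      return(radii[k])
  }
  NA_real_
}

#' Incremental-radius convergence scan with per-residue profile
#'
#' Runs the full decomposition: selects every residue within the largest
#' shell, builds its capped quartet once, evaluates its ligand
#' interaction energy at each dielectric (cached -- the quartet does not
#' depend on the shell), accumulates shell totals
#' `total(r, eps) = sum of member residues' energies`, and declares
#' convergence at the smallest radius whose total changed by less than
#' `tolerance` (relative) from the preceding radius at every dielectric
#' simultaneously.
#'
#' @param complex a parameterized [mfcc_complex()].
#' @param backend an [energy_backend()].
#' @param dielectrics dielectric constants to evaluate (default 10, 20, 40).
#' @param radii strictly increasing shell radii in Angstrom (default 2.0
#'   to 8.0 in 0.5 steps).
#' @param tolerance relative-change convergence threshold (default 0.10).
#' @param spec a [cap_spec()].
#' @return list with elements
#'   \describe{
#'     \item{scan}{class `convergence_scan`: `radii`, `shell_members`
#'       (list radius -> residue keys `"chain:resno"`), `totals` (radius x
#'       dielectric matrix, kcal/mol), `converged_radius` (Angstrom or
#'       `NA`), `tolerance`, `failures`.}
#'     \item{profile}{class `residue_profile`: one row per residue in the
#'       largest shell with `min_dist` and one `EI_<eps>` column per
#'       dielectric.}
#'   }
#' @export
run_scan <- function(complex, backend, dielectrics = c(10, 20, 40),
                     radii = seq(2, 8, by = 0.5), tolerance = 0.10,
                     spec = cap_spec()) {
  stopifnot(inherits(complex, "mfcc_complex"),
            inherits(backend, "energy_backend"),
            length(dielectrics) >= 1L, all(dielectrics > 0),
            length(radii) >= 2L, all(diff(radii) > 0), tolerance >= 0)
  md <- residue_min_distances(complex)
  members <- md[md$min_dist <= max(radii), , drop = FALSE]

  ecols <- paste0("EI_", dielectrics)
  profile <- members
  for (cc in ecols) profile[[cc]] <- NA_real_
  failures <- character(0)
  for (i in seq_len(nrow(members))) {
    res <- tryCatch({
      q <- build_quartet(complex, members$chain[i], members$resno[i], spec)
      vapply(dielectrics, function(eps)
        mfcc_interaction_energy(q, backend, eps), numeric(1))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s:%d -- %s", members$chain[i],
                                       members$resno[i],
                                       conditionMessage(e)))
      rep(NA_real_, length(dielectrics))
    })
    profile[i, ecols] <- as.list(res)
  }
  if (length(failures) > 0L)
    warning("energy evaluation failed for ", length(failures),
            " residue(s); partial results returned:\n  ",
            paste(failures, collapse = "\n  "), call. = FALSE)

  keys <- paste(profile$chain, profile$resno, sep = ":")
  shell_members <- lapply(radii, function(r) keys[profile$min_dist <= r])
  names(shell_members) <- sprintf("%g", radii)
  totals <- matrix(NA_real_, nrow = length(radii), ncol = length(dielectrics),
                   dimnames = list(sprintf("%g", radii), ecols))
  for (k in seq_along(radii)) {
    in_shell <- profile$min_dist <= radii[k]
    totals[k, ] <- vapply(ecols, function(cc)
      sum(profile[[cc]][in_shell]), numeric(1))
  }
  conv <- .converged_radius(totals, radii, tolerance)

  rownames(profile) <- NULL
  attr(profile, "dielectrics") <- dielectrics
  class(profile) <- c("residue_profile", "data.frame")
  scan <- structure(list(radii = radii, shell_members = shell_members,
                         totals = totals, converged_radius = conv,
                         tolerance = tolerance, failures = failures),
                    class = "convergence_scan")
  list(scan = scan, profile = profile)
}

#' @export
print.convergence_scan <- function(x, ...) {
  cat(sprintf(
    "convergence_scan: %d radii (%.1f-%.1f A), tolerance %.0f%%, converged at %s\n",
    length(x$radii), min(x$radii), max(x$radii), 100 * x$tolerance,
    if (is.na(x$converged_radius)) "none"
    else sprintf("%.1f A", x$converged_radius)))
  print(round(x$totals, 4))
  invisible(x)
}

#' Construct a per-residue energy profile from known values
#'
#' Builds a `residue_profile` directly from a table of per-residue
#' interaction energies (e.g. values reported by an external quantum
#' pipeline) so that [rank_residues()] and [group_sum()] apply to them.
#'
#' @param entries data.frame with `chain`, `resno`, `resid`, optionally
#'   `min_dist`, and one energy column per dielectric.
#' @param dielectrics numeric vector; entry `i` labels the `i`-th energy
#'   column `EI_<dielectrics[i]>`.
#' @param energy_cols names of the energy columns in `entries`, in the
#'   same order as `dielectrics` (default: `EI_<eps>` already present).
#' @return A `residue_profile`.
#' @export
residue_profile <- function(entries, dielectrics,
                            energy_cols = paste0("EI_", dielectrics)) {
  stopifnot(all(c("chain", "resno", "resid") %in% names(entries)),
            length(energy_cols) == length(dielectrics),
            all(energy_cols %in% names(entries)))
  out <- entries
  names(out)[match(energy_cols, names(out))] <- paste0("EI_", dielectrics)
  if (!("min_dist" %in% names(out))) out$min_dist <- NA_real_
  if (anyDuplicated(paste(out$chain, out$resno)) > 0L)
    stop("duplicate residue keys in profile entries", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "dielectrics") <- dielectrics
  class(out) <- c("residue_profile", "data.frame")
  out
}

.profile_col <- function(profile, dielectric) {
  cc <- paste0("EI_", dielectric)
  if (!(cc %in% names(profile)))
    stop("dielectric ", dielectric, " not present in profile (have: ",
         paste(attr(profile, "dielectrics"), collapse = ", "), ")",
         call. = FALSE)
  cc
}

#' Rank residues by interaction energy
#'
#' Sorts the profile most-negative (most attractive) first at the given
#' dielectric; ties are broken by (chain, seq).
#'
#' @param profile a `residue_profile`.
#' @param dielectric which dielectric's energies to rank by.
#' @return The profile rows in rank order.
#' @export
rank_residues <- function(profile, dielectric) {
  stopifnot(inherits(profile, "residue_profile"))
  cc <- .profile_col(profile, dielectric)
  out <- profile[order(profile[[cc]], profile$chain, profile$resno), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sum the interaction energies of named residues
#'
#' @param profile a `residue_profile`.
#' @param residue_keys character vector `"chain:resno"`, or a data.frame
#'   with `chain` and `resno` columns.
#' @param dielectric which dielectric's energies to sum.
#' @return Arithmetic sum in kcal/mol (0 for an empty key set).
#' @export
group_sum <- function(profile, residue_keys, dielectric) {
  stopifnot(inherits(profile, "residue_profile"))
  cc <- .profile_col(profile, dielectric)
  if (is.data.frame(residue_keys))
    residue_keys <- paste(residue_keys$chain, residue_keys$resno, sep = ":")
  if (length(residue_keys) == 0L) return(0)
  keys <- paste(profile$chain, profile$resno, sep = ":")
  idx <- match(residue_keys, keys)
  if (anyNA(idx))
    stop("residues not in profile: ",
         paste(residue_keys[is.na(idx)], collapse = ", "), call. = FALSE)
  sum(profile[[cc]][idx])
}
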