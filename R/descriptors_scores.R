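## Conceptual-DFT reactivity descriptors from frontier-orbital energies,
## and the weighted docking-score combination.

#' Conceptual-DFT descriptors from HOMO/LUMO energies
#'
#' Koopmans-style identification of the ionization potential and electron
#' affinity with the frontier-orbital energies, I = -E(HOMO) and
#' A = -E(LUMO), then
#' gap = I - A, hardness eta = (I - A)/2, softness sigma = 1/eta,
#' electronegativity chi = (I + A)/2, chemical potential mu = -chi, and
#' the electrophilicity index in two conventions:
#' `omega_standard = mu^2 / (2 eta)` (the Parr definition) and
#' `omega_alt = mu^2 * eta / 2`, which some published descriptor tables
#' use.  Both are always returned; `convention` selects which one fills
#' the `omega` column.  `mu_printed`/`chi_printed` carry the
#' opposite-sign orientation (mu positive, chi negative) that such tables
#' print.
#'
#' Rows with `homo >= lumo` have no meaningful hardness: `gap`/`eta` are
#' still reported but `sigma` and the omegas are `NA` and the row is
#' flagged in the `note` column.
#'
#' @param homo,lumo frontier-orbital energies in eV (vectorized).
#' @param convention `"standard"` (mu^2/2eta) or `"alt"` (mu^2 eta/2).
#' @param label optional row labels.
#' @return data.frame of class `descriptor_set`, all energies in eV
#'   (softness in 1/eV).
#' @export
descriptors_from_orbitals <- function(homo, lumo,
                                      convention = c("standard", "alt"),
                                      label = NULL) {
  convention <- match.arg(convention)
  stopifnot(length(homo) == length(lumo),
            all(is.finite(homo)), all(is.finite(lumo)))
  I <- -homo
  A <- -lumo
  gap <- I - A
  eta <- gap / 2
  ok <- eta > 0
  sigma <- ifelse(ok, 1 / eta, NA_real_)
  chi <- (I + A) / 2
  mu <- -chi
  omega_standard <- ifelse(ok, mu^2 / (2 * eta), NA_real_)
  omega_alt <- ifelse(ok, mu^2 * eta / 2, NA_real_)
  out <- data.frame(
    label = if (is.null(label)) sprintf("mol%d", seq_along(homo)) else label,
    homo = homo, lumo = lumo,
    I = I, A = A, gap = gap,
    eta = eta, sigma = sigma,
    mu = mu, chi = chi,
    mu_printed = -mu, chi_printed = -chi,
    omega_standard = omega_standard, omega_alt = omega_alt,
    omega = if (convention == "standard") omega_standard else omega_alt,
    convention = rep(convention, length(homo)),
    note = ifelse(ok, "", "non-positive HOMO-LUMO gap"),
    stringsAsFactors = FALSE)
  if (any(!ok))
    warning(sum(!ok), " row(s) with homo >= lumo: softness and ",
            "electrophilicity undefined", call. = FALSE)
  class(out) <- c("descriptor_set", "data.frame")
  out
}

#' Descriptor table from a TSV of orbital energies
#'
#' Reads a tab-separated file with columns `label`, `homo_eV`, `lumo_eV`
#' (or passes through a data.frame with those columns) and computes the
#' full descriptor set per row.  Malformed rows (non-numeric energies)
#' are flagged in the `note` column and left `NA`; the remaining rows are
#' processed normally.
#'
#' @param input path to a TSV file, or a data.frame.
#' @param convention passed to [descriptors_from_orbitals()].
#' @return A `descriptor_set` data.frame (zero rows for an empty input).
#' @export
descriptor_table <- function(input, convention = c("standard", "alt")) {
  convention <- match.arg(convention)
  df <- if (is.data.frame(input)) input
        else utils::read.delim(input, stringsAsFactors = FALSE)
  need <- c("label", "homo_eV", "lumo_eV")
  if (nrow(df) == 0L) {
    out <- descriptors_from_orbitals(numeric(0), numeric(0),
                                     convention = convention,
                                     label = character(0))
    return(out)
  }
  if (!all(need %in% names(df)))
    stop("orbital table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  homo <- suppressWarnings(as.numeric(df$homo_eV))
  lumo <- suppressWarnings(as.numeric(df$lumo_eV))
  bad <- !is.finite(homo) | !is.finite(lumo)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped: ",
            paste(df$label[bad], collapse = ", "), call. = FALSE)
    homo[bad] <- 0; lumo[bad] <- 0  # placeholder; overwritten with NA below
  }
  out <- suppressWarnings(
    descriptors_from_orbitals(homo, lumo, convention = convention,
                              label = as.character(df$label)))
  if (any(bad)) {
    num <- vapply(out, is.numeric, logical(1))
    out[bad, num] <- NA_real_
    out$note[bad] <- "malformed row"
  }
  out
}

#' Weighted docking-score combination
#'
#' The score used to rank docked poses: a fixed linear combination of
#' component energies,
#' `HS = 1.0 E_vdw + 0.2 E_elec + 1.0 E_desolv + 0.1 E_air`
#' (van der Waals, Coulomb electrostatics, desolvation, and ambiguous
#' restraint energies, all in kcal/mol).
#'
#' @param e_vdw,e_elec,e_desolv,e_air component energies in kcal/mol
#'   (vectorized).
#' @return Score in kcal/mol.
#' @export
haddock_score <- function(e_vdw, e_elec, e_desolv = 0, e_air = 0) {
  stopifnot(all(is.finite(e_vdw)), all(is.finite(e_elec)),
            all(is.finite(e_desolv)), all(is.finite(e_air)))
  1.0 * e_vdw + 0.2 * e_elec + 1.0 * e_desolv + 0.1 * e_air
}
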