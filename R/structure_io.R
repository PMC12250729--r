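## Structure input/output: PDB/PQR reading (via bio3d), XYZ and PQR
## writing, and per-atom parameter assignment.

#' Conversion constant: one Hartree in kcal/mol
#' @export
HARTREE_KCAL <- 627.509474

#' Coulomb constant in kcal*Angstrom/(mol*e^2)
#' @export
COULOMB_KCAL <- 332.0637

.elem_from_name <- function(name) {
  ## strip leading digits, take leading letters; two-letter halogens and
  ## common metals recognised, otherwise first letter
  core <- sub("^[0-9']+", "", name)
  core <- toupper(sub("([A-Za-z]+).*", "\\1", core))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA")
  ## "CA"/"NA" as element only when the full atom name is exactly that is
  ## ambiguous with C-alpha; PDB convention resolves via the element column,
  ## which is preferred whenever present.  Here CA/NA default to C/N.
  if (substr(core, 1, 2) %in% setdiff(two, c("CA", "NA")))
    return(paste0(substr(core, 1, 1), tolower(substr(core, 2, 2))))
  substr(core, 1, 1)
}

#' Read a protein-ligand complex from PDB or PQR
#'
#' Parses a structure file and splits it into sequence-ordered polymer
#' residues plus one ligand group.  PQR files carry per-atom partial
#' charges and radii (the two whitespace-delimited columns after the
#' coordinates); the radius is stored as the Lennard-Jones `rmin2`
#' half-distance and well depths are left at zero until
#' [assign_parameters()] supplies them.  PDB files yield zero charges.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"pqr"`.
#' @param ligand ligand selector: either a residue-name string (matched
#'   against all residue names, the PDB convention for HETATM ligands) or a
#'   `list(chain =, resno =)` pair.  Must match exactly one residue group.
#'
#' @return An [mfcc_complex()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr"),
                           ligand = "LIG") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pqr") bio3d::read.pqr(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e)
      stop("failed to parse ", path, " as ", toupper(format), ": ",
           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no ATOM/HETATM records in ", path, call. = FALSE)

  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- vapply(at$elety[bad], .elem_from_name, character(1))
  elem <- trimws(elem)

  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    elem = elem,
    x = at$x, y = at$y, z = at$z,
    charge = if (format == "pqr") at$o else 0,
    eps = 0,
    rmin2 = if (format == "pqr") at$b else 0,
    chain = chain,
    resno = as.integer(at$resno),
    resid = trimws(at$resid),
    ligand = FALSE,
    role = "source",
    stringsAsFactors = FALSE)

  ## resolve ligand selector
  grp <- unique(atoms[, c("chain", "resno", "resid")])
  if (is.character(ligand) && length(ligand) == 1L) {
    hit <- grp[grp$resid == ligand, , drop = FALSE]
    if (nrow(hit) == 0L)
      stop("ligand selector '", ligand, "' matches no residue group",
           call. = FALSE)
    if (nrow(hit) > 1L)
      stop("ligand selector '", ligand, "' matches ", nrow(hit),
           " residue groups; disambiguate with list(chain=, resno=)",
           call. = FALSE)
  } else if (is.list(ligand) && all(c("chain", "resno") %in% names(ligand))) {
    hit <- grp[grp$chain == ligand$chain & grp$resno == ligand$resno, ,
               drop = FALSE]
    if (nrow(hit) != 1L)
      stop("ligand selector chain=", ligand$chain, " resno=", ligand$resno,
           " matches ", nrow(hit), " residue groups", call. = FALSE)
  } else {
    stop("ligand selector must be a residue-name string or list(chain=, resno=)",
         call. = FALSE)
  }
  atoms$ligand <- atoms$chain == hit$chain & atoms$resno == hit$resno

  cx <- mfcc_complex(atoms, source = path)

  ## warn about polymer residues lacking backbone N/C (non-cleavable)
  rt <- residue_table(cx)
  nc <- character(0)
  for (i in seq_len(nrow(rt))) {
    ra <- residue_atoms(cx, rt$chain[i], rt$resno[i])
    if (!all(c("N", "C") %in% ra$name))
      nc <- c(nc, paste0(rt$chain[i], ":", rt$resno[i]))
  }
  if (length(nc) > 0L) {
    warning("polymer residues lacking backbone N/C (non-cleavable): ",
            paste(nc, collapse = ", "), call. = FALSE)
    attr(cx, "noncleavable") <- nc
  }
  cx
}

#' Write an atom system as PQR
#'
#' Fixed-width PDB-like records with partial charge and radius after the
#' coordinates; reading the file back with [read_structure()] reproduces
#' atom count, group partition and charges exactly (charges are written to
#' 4 decimals, radii to 4 decimals).
#'
#' @param complex an [mfcc_complex()] or a plain atom data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(complex, path) {
  atoms <- if (inherits(complex, "mfcc_complex")) complex$atoms else complex
  .check_atoms(atoms)
  rec <- ifelse(atoms$ligand, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%8.4f%8.4f",
                   rec, atoms$serial, atoms$name, atoms$resid, atoms$chain,
                   atoms$resno, atoms$x, atoms$y, atoms$z,
                   atoms$charge, atoms$rmin2)
  con <- file(path, "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  writeLines(c(lines, "END"), con, sep = "\n")
  invisible(path)
}

#' Write an atom system as XYZ
#'
#' Standard XYZ layout: atom count, comment line, then one
#' `element x y z` line per atom with 8 decimal places.
#'
#' @param system atom data.frame (any object with `elem`, `x`, `y`, `z`).
#' @param path output path.
#' @param comment second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, comment = "") {
  if (is.null(nrow(system)) || nrow(system) == 0L)
    stop("cannot write an empty system as XYZ", call. = FALSE)
  lines <- c(sprintf("%d", nrow(system)),
             gsub("[\r\n]", " ", comment),
             sprintf("%-2s %14.8f %14.8f %14.8f",
                     system$elem, system$x, system$y, system$z))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path file path.
#' @return data.frame with `elem`, `x`, `y`, `z` and the comment line as
#'   attribute `"comment"`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("not an XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < 2L + n)
    stop("malformed XYZ file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  out <- data.frame(
    elem = vapply(toks, `[`, character(1), 1L),
    x = as.numeric(vapply(toks, `[`, character(1), 2L)),
    y = as.numeric(vapply(toks, `[`, character(1), 3L)),
    z = as.numeric(vapply(toks, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  attr(out, "comment") <- lines[2]
  out
}

#' Assign charges and Lennard-Jones parameters from a lookup table
#'
#' Looks each atom up by `(res_name, atom_name)`; atoms without a specific
#' entry fall back to an element-level row (`res_name` `NA` or `"*"`).
#' Every atom must be covered one way or the other.
#'
#' @param complex an [mfcc_complex()].
#' @param table data.frame with columns `resid` (3-letter residue name, or
#'   `NA`/`"*"` for element fallback rows), `name` (atom name, `NA`/`"*"`
#'   for fallback rows), `elem`, `charge` (e), `eps` (kcal/mol),
#'   `rmin2` (Angstrom).
#' @return The complex with all atoms parameterized.  The net polymer and
#'   ligand charges are reported via `message()`.
#' @export
assign_parameters <- function(complex, table) {
  stopifnot(inherits(complex, "mfcc_complex"))
  atoms <- complex$atoms
  tab <- table
  tab$resid[is.na(tab$resid)] <- "*"
  tab$name[is.na(tab$name)] <- "*"
  specific <- tab[tab$resid != "*" & tab$name != "*", , drop = FALSE]
  fallback <- tab[tab$resid == "*" | tab$name == "*", , drop = FALSE]

  skey <- paste(specific$resid, specific$name)
  fkey <- fallback$elem
  uncovered <- character(0)
  for (i in seq_len(nrow(atoms))) {
    j <- match(paste(atoms$resid[i], atoms$name[i]), skey)
    if (is.na(j)) {
      k <- match(atoms$elem[i], fkey)
      if (is.na(k)) {
        uncovered <- c(uncovered,
                       sprintf("%s:%d %s/%s (%s)", atoms$chain[i],
                               atoms$resno[i], atoms$resid[i],
                               atoms$name[i], atoms$elem[i]))
        next
      }
      atoms$charge[i] <- fallback$charge[k]
      atoms$eps[i] <- fallback$eps[k]
      atoms$rmin2[i] <- fallback$rmin2[k]
    } else {
      atoms$charge[i] <- specific$charge[j]
      atoms$eps[i] <- specific$eps[j]
      atoms$rmin2[i] <- specific$rmin2[j]
    }
  }
  if (length(uncovered) > 0L)
    stop("parameter table does not cover: ",
         paste(uncovered, collapse = "; "), call. = FALSE)
  complex$atoms <- atoms
  message(sprintf("net polymer charge: %+.4f e; net ligand charge: %+.4f e",
                  sum(atoms$charge[!atoms$ligand]),
                  sum(atoms$charge[atoms$ligand])))
  complex
}
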