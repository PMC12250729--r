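## Synthetic protein-ligand complexes with known ground-truth energetics.
## The generator builds a glycine-like extended chain, docks a small rigid
## ligand cluster at controlled minimum distances from chosen residues,
## assigns charges and LJ parameters, and computes ground-truth pairwise
## ligand-residue energies with a deliberately naive scalar double loop
## that shares no code with the vectorized backend.

#' Specify a synthetic complex fixture
#'
#' @param n_residues number of residues in the chain (>= 3).
#' @param ligand_atoms number of ligand atoms (3-10).
#' @param placements data.frame with columns `residue` (1-based index)
#'   and `distance` (target minimum ligand-residue distance, Angstrom,
#'   >= 1.5); the ligand is rigidly translated until every target is met
#'   within 0.05 Angstrom.
#' @param charge_scheme `"random"` (uniform in +-0.4 e, 4 decimals),
#'   `"zero"`, or `"decaying"` (per-residue magnitudes shrink with
#'   residue index so shell totals converge).
#' @param lj_scheme `"amber_like"` (element-level well depths/radii) or
#'   `"none"` (pure Coulomb -- used for dielectric-scaling checks).
#' @param net_ligand_charge declared net ligand charge in e; the last
#'   ligand atom absorbs the rounding remainder so the sum is exact.
#' @param side_chain add a one-atom side-chain pseudo-atom (CB) per
#'   residue to exercise side-chain inclusion in the caps.
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 3,
                         ligand_atoms = 4,
                         placements = data.frame(residue = 1, distance = 2.5),
                         charge_scheme = c("random", "zero", "decaying"),
                         lj_scheme = c("amber_like", "none"),
                         net_ligand_charge = 0,
                         side_chain = FALSE,
                         seed = 1L) {
  charge_scheme <- match.arg(charge_scheme)
  lj_scheme <- match.arg(lj_scheme)
  stopifnot(n_residues >= 3, ligand_atoms >= 3, ligand_atoms <= 10,
            is.data.frame(placements),
            all(c("residue", "distance") %in% names(placements)),
            all(placements$residue >= 1),
            all(placements$residue <= n_residues),
            all(placements$distance >= 1.5))
  structure(list(n_residues = as.integer(n_residues),
                 ligand_atoms = as.integer(ligand_atoms),
                 placements = placements, charge_scheme = charge_scheme,
                 lj_scheme = lj_scheme,
                 net_ligand_charge = net_ligand_charge,
                 side_chain = isTRUE(side_chain), seed = as.integer(seed)),
            class = "fixture_spec")
}

.lj_table <- function(scheme) {
  if (scheme == "none")
    return(data.frame(elem = c("H", "C", "N", "O"), eps = 0, rmin2 = 0,
                      stringsAsFactors = FALSE))
  data.frame(elem = c("H", "C", "N", "O"),
             eps = c(0.0157, 0.0860, 0.1700, 0.2100),
             rmin2 = c(0.6000, 1.9080, 1.8240, 1.6612),
             stringsAsFactors = FALSE)
}

## extended glycine-like chain along x: 3.8 A CA-CA spacing, peptide
## C(i)-N(i+1) distance 1.4 A
.build_chain <- function(n_residues, side_chain) {
  rows <- list()
  serial <- 1L
  for (i in seq_len(n_residues)) {
    x0 <- 3.8 * (i - 1L)
    tmpl <- rbind(
      data.frame(name = "N",  elem = "N", x = x0 - 1.20, y = 0.60, z = 0),
      data.frame(name = "H",  elem = "H", x = x0 - 1.20, y = 1.61, z = 0),
      data.frame(name = "CA", elem = "C", x = x0,        y = 0.00, z = 0),
      data.frame(name = "C",  elem = "C", x = x0 + 1.20, y = 0.60, z = 0),
      data.frame(name = "O",  elem = "O", x = x0 + 1.40, y = 1.81, z = 0))
    if (side_chain)
      tmpl <- rbind(tmpl, data.frame(name = "CB", elem = "C",
                                     x = x0, y = -1.53, z = 0))
    tmpl$serial <- seq.int(serial, length.out = nrow(tmpl))
    serial <- serial + nrow(tmpl)
    tmpl$chain <- "A"
    tmpl$resno <- i
    tmpl$resid <- "GLY"
    rows[[i]] <- tmpl
  }
  out <- do.call(rbind, rows)
  out$charge <- 0; out$eps <- 0; out$rmin2 <- 0
  out$ligand <- FALSE; out$role <- "source"
  rownames(out) <- NULL
  out[, .atom_cols]
}

## rigid ligand template centred at the origin: atoms on a ring with
## alternating z, ring radius scaled so no two atoms come closer than
## ~1.5 A (bond-length scale, keeps LJ energies numerically benign)
.ligand_template <- function(k) {
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  r_ring <- max(0.9, 0.664 / sin(pi / k))
  data.frame(name = sprintf("C%d", seq_len(k)), elem = "C",
             x = r_ring * cos(ang), y = r_ring * sin(ang),
             z = 0.35 * rep_len(c(-1, 1), k),
             stringsAsFactors = FALSE)
}

## rigid-body transform of the template: rotate about its centroid by
## Euler angles p[4:6], then translate by p[1:3]
.place_transform <- function(tpl, p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  xyz <- t(Rz %*% Ry %*% Rx %*% t(cbind(tpl$x, tpl$y, tpl$z)))
  out <- tpl
  out$x <- xyz[, 1] + p[1]
  out$y <- xyz[, 2] + p[2]
  out$z <- xyz[, 3] + p[3]
  out
}

## minimum distance from a placed template to one residue's atoms
.place_mindist <- function(tpl, res) {
  min(sqrt(outer(tpl$x, res$x, `-`)^2 +
           outer(tpl$y, res$y, `-`)^2 +
           outer(tpl$z, res$z, `-`)^2))
}

.place_ligand <- function(tpl, chain_atoms, placements) {
  res_list <- lapply(placements$residue, function(i)
    chain_atoms[chain_atoms$resno == i, , drop = FALSE])
  ## non-target residues must keep >= 1.5 A clearance so fixture energies
  ## stay in a numerically benign range
  other <- setdiff(unique(chain_atoms$resno), placements$residue)
  other_list <- lapply(other, function(i)
    chain_atoms[chain_atoms$resno == i, , drop = FALSE])
  obj <- function(p) {
    placed <- .place_transform(tpl, p)
    err <- vapply(seq_along(res_list), function(j)
      .place_mindist(placed, res_list[[j]]) - placements$distance[j],
      numeric(1))
    pen <- 0
    for (res in other_list)
      pen <- pen + max(0, 1.5 - .place_mindist(placed, res))^2
    sum(err^2) + 10 * pen
  }
  ## starting points: above the first target residue at roughly the
  ## requested clearance, with a few lateral/vertical alternatives
  ca <- res_list[[1]][res_list[[1]]$name == "CA", , drop = FALSE]
  d1 <- placements$distance[1]
  starts <- list(c(ca$x, ca$y + d1 + 1.2, 0),
                 c(ca$x, ca$y - d1 - 2.6, 0),
                 c(ca$x + 1.5, ca$y + d1 + 1.2, 1.0),
                 c(ca$x, ca$y + d1 + 1.2, d1),
                 c(ca$x - 1.5, 0, d1 + 1.8))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(c(s, 0, 0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-12) break
  }
  ## polish: restart the simplex from the best point (plus deterministic
  ## jitters to escape kinks of the min-distance surface) until it stalls
  jitters <- rbind(rep(0, 6),
                   cbind(0.25 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                         matrix(0.3, 6, 3)))
  for (pass in 1:6) {
    improved <- FALSE
    for (r in seq_len(nrow(jitters))) {
      fit <- stats::optim(best$par + jitters[r, ], obj,
                          method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-15))
      if (fit$value < best$value - 1e-13) {
        best <- fit
        improved <- TRUE
      }
    }
    if (!improved || best$value < 1e-14) break
  }
  placed <- .place_transform(tpl, best$par)
  err <- vapply(seq_along(res_list), function(j)
    abs(.place_mindist(placed, res_list[[j]]) - placements$distance[j]),
    numeric(1))
  if (any(err > 0.05))
    stop("infeasible ligand placement: achieved distances miss targets by ",
         paste(sprintf("%.3f", err), collapse = ", "), " A", call. = FALSE)
  placed
}

## ---- naive ground-truth oracle -------------------------------------------
## scalar double loops, no code shared with classical_energy/pairsum

.naive_pair_energy <- function(lig, res, dielectric) {
  e <- 0
  for (a in seq_len(nrow(lig))) {
    for (b in seq_len(nrow(res))) {
      dx <- lig$x[a] - res$x[b]
      dy <- lig$y[a] - res$y[b]
      dz <- lig$z[a] - res$z[b]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      e <- e + 332.0637 * lig$charge[a] * res$charge[b] / (dielectric * r)
      eab <- sqrt(lig$eps[a] * res$eps[b])
      if (eab > 0) {
        s <- (lig$rmin2[a] + res$rmin2[b]) / r
        e <- e + eab * (s^12 - 2 * s^6)
      }
    }
  }
  e
}

.naive_min_dist <- function(lig, res) {
  best <- Inf
  for (a in seq_len(nrow(lig)))
    for (b in seq_len(nrow(res))) {
      d <- sqrt((lig$x[a] - res$x[b])^2 + (lig$y[a] - res$y[b])^2 +
                (lig$z[a] - res$z[b])^2)
      if (d < best) best <- d
    }
  best
}

.ground_truth <- function(atoms, dielectrics, radii, tolerance) {
  lig <- atoms[atoms$ligand, , drop = FALSE]
  resnos <- sort(unique(atoms$resno[!atoms$ligand]))
  pair <- matrix(NA_real_, nrow = length(resnos), ncol = length(dielectrics),
                 dimnames = list(as.character(resnos),
                                 sprintf("%g", dielectrics)))
  mind <- numeric(length(resnos))
  for (i in seq_along(resnos)) {
    res <- atoms[!atoms$ligand & atoms$resno == resnos[i], , drop = FALSE]
    mind[i] <- .naive_min_dist(lig, res)
    for (j in seq_along(dielectrics))
      pair[i, j] <- .naive_pair_energy(lig, res, dielectrics[j])
  }
  shells <- lapply(radii, function(r) resnos[mind <= r])
  names(shells) <- sprintf("%g", radii)
  totals <- matrix(NA_real_, nrow = length(radii), ncol = length(dielectrics),
                   dimnames = list(sprintf("%g", radii),
                                   sprintf("%g", dielectrics)))
  for (k in seq_along(radii)) {
    inr <- mind <= radii[k]
    for (j in seq_along(dielectrics)) totals[k, j] <- sum(pair[inr, j])
  }
  ## same successive-radius rule, written independently
  conv <- NA_real_
  for (k in 2:length(radii)) {
    prev <- totals[k - 1L, ]
    if (any(prev == 0)) next
    rel <- abs(totals[k, ] - prev) / abs(prev)
    if (all(rel < tolerance)) { conv <- radii[k]; break }
  }
  list(residues = resnos, min_dist = mind, pair_energies = pair,
       shell_membership = shells, shell_totals = totals,
       converged_radius = conv,
       total_at_max_radius = totals[length(radii), , drop = TRUE])
}

#' Generate a synthetic complex with ground-truth energetics
#'
#' Deterministic for a given spec (seeded RNG): builds the chain, places
#' the ligand to hit each requested minimum distance within 0.05
#' Angstrom, assigns charges and LJ parameters, and computes ground-truth
#' per-residue pair energies, shell membership, shell totals and the
#' converged radius with an independent naive implementation of the same
#' pair formula as [classical_energy()].
#'
#' @param spec a [fixture_spec()].
#' @param dir if non-`NULL`, write `complex.pqr` and `ground_truth.json`
#'   there (created if needed).
#' @param dielectrics,radii,tolerance ground-truth evaluation grid
#'   (defaults match [run_scan()]).
#' @return list with `complex` (a parameterized [mfcc_complex()]),
#'   `truth` (the ground-truth list), `lj_table`, and -- when `dir` is
#'   given -- `pqr_path` and `truth_path`.
#' @export
generate_complex <- function(spec, dir = NULL, dielectrics = c(10, 20, 40),
                             radii = seq(2, 8, by = 0.5), tolerance = 0.10) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  chain <- .build_chain(spec$n_residues, spec$side_chain)
  tpl <- .ligand_template(spec$ligand_atoms)
  placed <- .place_ligand(tpl, chain, spec$placements)

  lig <- data.frame(serial = max(chain$serial) + seq_len(nrow(tpl)),
                    name = placed$name, elem = placed$elem,
                    x = placed$x, y = placed$y, z = placed$z,
                    charge = 0, eps = 0, rmin2 = 0,
                    chain = "B", resno = 1L, resid = "LIG",
                    ligand = TRUE, role = "source",
                    stringsAsFactors = FALSE)

  ## charges
  if (spec$charge_scheme == "random") {
    chain$charge <- round(stats::runif(nrow(chain), -0.4, 0.4), 4)
  } else if (spec$charge_scheme == "decaying") {
    ## per-residue magnitude shrinks with the residue's distance from the
    ## placed ligand, so successive shells add progressively smaller
    ## contributions and the shell-total series stabilizes
    mind <- vapply(sort(unique(chain$resno)), function(i)
      .place_mindist(placed, chain[chain$resno == i, , drop = FALSE]),
      numeric(1))
    scale <- exp(-0.8 * (mind - min(mind)))[chain$resno]
    base <- round(stats::runif(nrow(chain), 0.15, 0.35), 4)
    ## residue charges oppose the ligand's net charge: attractive pocket
    chain$charge <- round(-sign(spec$net_ligand_charge + 0.5) * base * scale, 4)
  } # "zero": leave at 0
  if (spec$charge_scheme != "zero") {
    lig$charge <- round(stats::runif(nrow(lig), -0.4, 0.4), 4)
    lig$charge[nrow(lig)] <- round(
      spec$net_ligand_charge - sum(lig$charge[-nrow(lig)]), 4)
  }

  ## LJ parameters
  ljt <- .lj_table(spec$lj_scheme)
  for (df in c("chain", "lig")) {
    a <- get(df)
    k <- match(a$elem, ljt$elem)
    a$eps <- ljt$eps[k]
    a$rmin2 <- ljt$rmin2[k]
    assign(df, a)
  }

  atoms <- rbind(chain, lig)
  cx <- mfcc_complex(atoms, source = "synthetic")
  truth <- .ground_truth(atoms, dielectrics, radii, tolerance)
  truth$spec <- list(n_residues = spec$n_residues,
                     ligand_atoms = spec$ligand_atoms,
                     charge_scheme = spec$charge_scheme,
                     lj_scheme = spec$lj_scheme,
                     net_ligand_charge = spec$net_ligand_charge,
                     seed = spec$seed, tolerance = tolerance)
  out <- list(complex = cx, truth = truth, lj_table = ljt)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$pqr_path <- file.path(dir, "complex.pqr")
    out$truth_path <- file.path(dir, "ground_truth.json")
    write_pqr(cx, out$pqr_path)
    jsonlite::write_json(truth, out$truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  out
}

#' Decaying-energy fixture for convergence checks
#'
#' A 10-residue chain with the ligand parked near residue 3 and
#' per-residue charge magnitudes shrinking geometrically along the chain,
#' so that the shell-total series stabilizes (relative change below the
#' tolerance) at a radius recorded in the ground truth.
#'
#' @param seed RNG seed.
#' @param dir optional output directory (as in [generate_complex()]).
#' @param tolerance convergence tolerance used for the recorded
#'   ground-truth radius.
#' @return As [generate_complex()].
#' @export
decaying_energy_fixture <- function(seed = 1L, dir = NULL, tolerance = 0.10) {
  spec <- fixture_spec(
    n_residues = 10, ligand_atoms = 5,
    placements = data.frame(residue = 3, distance = 2.2),
    charge_scheme = "decaying", lj_scheme = "none",
    net_ligand_charge = 1, seed = seed)
  generate_complex(spec, dir = dir, tolerance = tolerance)
}
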