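test_that("distance shells follow the constructed fixture geometry", {
  g <- three_residue_complex()  # target min distances 2.1 / 3.4 / 5.9 A
  expect_identical(residues_within(g$complex, 2.5)$resno, 1L)
  expect_identical(residues_within(g$complex, 3.5)$resno, c(1L, 2L))
  expect_identical(residues_within(g$complex, 6.0)$resno, c(1L, 2L, 3L))
  ## radius below the closest contact: empty shell allowed
  expect_identical(nrow(residues_within(g$complex, 1.0)), 0L)
  ## reported distances match the generator's ground truth
  md <- residue_min_distances(g$complex)
  expect_equal(md$min_dist, g$truth$min_dist, tolerance = 1e-9)
})

test_that("shells are nested and totals equal shell-restricted sums", {
  d <- decaying_energy_fixture(seed = 5)
  out <- suppressMessages(run_scan(d$complex, ghost_backend()))
  sm <- out$scan$shell_members
  for (k in seq_along(sm)[-1L])
    expect_true(all(sm[[k - 1L]] %in% sm[[k]]))
  ## sum consistency at every radius and dielectric, exactly
  prof <- out$profile
  for (k in seq_along(out$scan$radii)) {
    keys <- sm[[k]]
    for (eps in c(10, 20, 40)) {
      tot <- out$scan$totals[k, paste0("EI_", eps)]
      expect_identical(tot, group_sum(prof, keys, eps))
    }
  }
})

test_that("convergence rule picks the first stabilized successor radius", {
  ## shell totals -10, -12, -12.5, -12.6: changes 20%, 4.17%, 0.8%
  totals <- matrix(c(-10, -12, -12.5, -12.6), ncol = 1)
  radii <- c(2, 2.5, 3, 3.5)
  expect_identical(fragbind:::.converged_radius(totals, radii, 0.10), 3)
  ## strict zero tolerance never converges
  expect_identical(fragbind:::.converged_radius(totals, radii, 0),
                   NA_real_)
  ## zero totals are skipped, not divided by
  tot0 <- matrix(c(0, -5, -5.2), ncol = 1)
  expect_message(
    r <- fragbind:::.converged_radius(tot0, c(2, 2.5, 3), 0.10),
    "skipped")
  expect_identical(r, 3)
  ## the criterion must hold at every dielectric simultaneously
  tot2 <- cbind(c(-10, -10.5, -10.6), c(-10, -16, -16.1))
  expect_identical(fragbind:::.converged_radius(tot2, c(2, 2.5, 3), 0.10), 3)
})

test_that("scan reproduces ground-truth energies, radius and membership", {
  d <- decaying_energy_fixture(seed = 2)
  out <- suppressMessages(run_scan(d$complex, ghost_backend()))
  ## converged radius agrees with the independently coded ground truth
  expect_identical(out$scan$converged_radius, d$truth$converged_radius)
  ## per-residue energies match the naive double loop
  keys <- paste(out$profile$chain, out$profile$resno, sep = ":")
  truth_idx <- match(out$profile$resno, d$truth$residues)
  for (j in seq_along(c(10, 20, 40))) {
    eps <- c(10, 20, 40)[j]
    expect_equal(out$profile[[paste0("EI_", eps)]],
                 unname(d$truth$pair_energies[truth_idx, j]),
                 tolerance = 1e-8)
  }
  ## membership at every radius agrees
  for (r in names(out$scan$shell_members)) {
    got <- sort(as.integer(sub("A:", "", out$scan$shell_members[[r]])))
    expect_identical(got, as.integer(d$truth$shell_membership[[r]]))
  }
})

test_that("single-residue shells carry exactly that residue's energy", {
  g <- generate_complex(fixture_spec(
    n_residues = 3, ligand_atoms = 3,
    placements = data.frame(residue = 1, distance = 2.0),
    charge_scheme = "random", lj_scheme = "none", seed = 9))
  out <- suppressMessages(run_scan(g$complex, ghost_backend()))
  first_shells <- which(vapply(out$scan$shell_members, length,
                               integer(1)) == 1L)
  e1 <- out$profile$EI_10[out$profile$resno == 1]
  for (k in first_shells)
    expect_identical(out$scan$totals[k, "EI_10"], e1)
})

test_that("ranking is most-negative-first with sequence-order tie-break", {
  prof <- residue_profile(
    data.frame(chain = "A", resno = c(1L, 2L, 3L),
               resid = c("ALA", "GLY", "SER"),
               EI_10 = c(-1.0, -5.0, -3.0)),
    dielectrics = 10)
  expect_identical(rank_residues(prof, 10)$resno, c(2L, 3L, 1L))
  tied <- residue_profile(
    data.frame(chain = "A", resno = c(2L, 1L), resid = "GLY",
               EI_10 = c(-3.0, -3.0)),
    dielectrics = 10)
  expect_identical(rank_residues(tied, 10)$resno, c(1L, 2L))
  expect_error(rank_residues(prof, 99), "not present")
})

test_that("group sums add the named residues' printed energies", {
  ## the four dominant pocket residues of the lemborexant-receptor
  ## complex, as reported by the reference per-residue decomposition
  prof <- residue_profile(
    data.frame(chain = "A", resno = c(344L, 130L, 311L, 126L),
               resid = c("HIS", "VAL", "TYR", "GLN"),
               EI_40 = c(-5.43, -4.93, -4.54, -4.38)),
    dielectrics = 40)
  expect_equal(group_sum(prof, c("A:344", "A:130", "A:311", "A:126"), 40),
               -19.28, tolerance = 1e-9)
  expect_identical(group_sum(prof, character(0), 40), 0)
  expect_error(group_sum(prof, "A:999", 40), "not in profile")
  ## summing every residue reproduces the full-profile total
  expect_equal(group_sum(prof, paste0("A:", prof$resno), 40),
               sum(prof$EI_40), tolerance = 1e-12)
})
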