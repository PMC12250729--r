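test_that("classical energy matches hand-evaluated Coulomb and edge cases", {
  ## two +0.5 e charges at 2.0 A, eps = 10: 332.0637 * 0.25 / 20
  sys <- two_atom_system(0.5, 0.5, 2.0)
  expect_equal(classical_energy(sys, 10), 332.0637 * 0.25 / 20,
               tolerance = 1e-12)
  ## single atom: no pairs
  expect_identical(classical_energy(sys[1, ], 10), 0)
  ## all charges zero, no LJ depth
  expect_identical(classical_energy(two_atom_system(0, 0, 2.0), 10), 0)
  ## LJ minimum: at r = rmin the well depth is recovered exactly
  syslj <- two_atom_system(0, 0, r = 3.0, eps = c(0.2, 0.2),
                           rmin2 = c(1.5, 1.5))
  expect_equal(classical_energy(syslj, 10), -0.2, tolerance = 1e-12)
  ## clash detection names the pair
  expect_error(classical_energy(two_atom_system(0, 0, 0.05), 10), "clash")
})

test_that("pairsum is a symmetric brute-force oracle", {
  a <- two_atom_system(1, 0, 0)[1, ]
  b <- two_atom_system(-1, 0, 0)[1, ]
  b$x <- 3.320637
  ## 332.0637 / 3.320637 = 100 exactly by construction
  expect_equal(pairsum(a, b, 1), -100, tolerance = 1e-9)
  expect_identical(pairsum(a[0, ], b, 1), 0)
  g <- three_residue_complex(seed = 21)
  lig <- ligand_atoms(g$complex)
  r1 <- residue_atoms(g$complex, "A", 1)
  expect_equal(pairsum(lig, r1, 10), pairsum(r1, lig, 10), tolerance = 1e-12)
  expect_error(pairsum(lig, lig, 10), "overlap")
})

test_that("classical energy is additive over subsystems", {
  g <- three_residue_complex(seed = 31)
  a <- residue_atoms(g$complex, "A", 1)
  b <- ligand_atoms(g$complex)
  lhs <- classical_energy(rbind(a, b), 20)
  rhs <- classical_energy(a, 20) + classical_energy(b, 20) + pairsum(a, b, 20)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("Coulomb-only energies scale exactly as 1/dielectric", {
  g <- three_residue_complex(seed = 41, lj_scheme = "none")
  sys <- g$complex$atoms
  e10 <- classical_energy(sys, 10)
  expect_equal(classical_energy(sys, 20), e10 / 2, tolerance = 1e-14)
  expect_equal(classical_energy(sys, 40), e10 / 4, tolerance = 1e-14)
})

test_that("classical energy is invariant to rigid-body motion", {
  g <- three_residue_complex(seed = 51)
  sys <- g$complex$atoms
  e0 <- classical_energy(sys, 10)
  ## translate
  tr <- sys
  tr$x <- tr$x + 12.3; tr$y <- tr$y - 4.5; tr$z <- tr$z + 0.7
  expect_equal(classical_energy(tr, 10), e0, tolerance = 1e-9)
  ## rotate about z by 37 degrees
  th <- 37 * pi / 180
  rot <- sys
  rot$x <- cos(th) * sys$x - sin(th) * sys$y
  rot$y <- sin(th) * sys$x + cos(th) * sys$y
  expect_equal(classical_energy(rot, 10), e0, tolerance = 1e-9)
})

test_that("quantum-job emitter applies the net-charge rounding rule", {
  sys <- two_atom_system(0.5, 0.48, 3.0)  # sum 0.98 -> +1
  p <- withr::local_tempfile(fileext = ".inp")
  emit_qm_input(sys, qm_job_spec(dielectric = 20), p)
  lines <- readLines(p)
  expect_match(lines[1], "B97D")
  expect_match(lines[1], "eps=20")
  expect_identical(lines[5], "1 1")
  expect_identical(length(grep("^C ", lines)), 2L)
  ## summed charge -0.5: ambiguous, caller must decide
  expect_error(emit_qm_input(two_atom_system(-0.25, -0.25, 3.0),
                             qm_job_spec(), p), "0.3 e")
  ## explicit net charge overrides the sum
  emit_qm_input(two_atom_system(-0.25, -0.25, 3.0),
                qm_job_spec(net_charge = -1L), p)
  expect_identical(readLines(p)[5], "-1 1")
})

test_that("energy parser converts Hartree and takes the last match", {
  p <- withr::local_tempfile(lines = c("junk", "ENERGY = -1.000000", "end"))
  expect_equal(parse_qm_energy(p), -627.509474, tolerance = 1e-9)
  p2 <- withr::local_tempfile(lines = c("ENERGY = -1.0", "ENERGY = -2.0"))
  expect_message(v <- parse_qm_energy(p2), "last")
  expect_equal(v, -2 * 627.509474, tolerance = 1e-9)
  p3 <- withr::local_tempfile(lines = "no energies here")
  expect_error(parse_qm_energy(p3), "no energy line")
})

test_that("a mock external runner recovers the classical energy", {
  ## emit an input, compute the classical energy, print it in Hartree the
  ## way an external code would, and parse it back
  g <- three_residue_complex(seed = 61)
  q <- build_quartet(g$complex, "A", 2)
  dir <- withr::local_tempdir()
  inp <- file.path(dir, "job.inp")
  outp <- file.path(dir, "job.out")
  emit_qm_input(q$sys_cap_r_cap, qm_job_spec(dielectric = 10,
                                             net_charge = 0L), inp)
  e_ref <- classical_energy(q$sys_cap_r_cap, 10)
  writeLines(c("mock quantum output",
               sprintf("FINAL ENERGY = %.12f Ha", e_ref / HARTREE_KCAL)),
             outp)
  expect_equal(parse_qm_energy(outp), e_ref, tolerance = 1e-6)
})
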