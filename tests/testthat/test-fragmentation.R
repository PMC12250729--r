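test_that("middle residue of a 3-residue chain: caps are true termini", {
  g <- three_residue_complex()
  cx <- g$complex
  n_chain <- sum(!cx$atoms$ligand)
  n_lig <- sum(cx$atoms$ligand)
  q <- build_quartet(cx, "A", 2)
  ## caps are the chain termini: no i-2/i+2 bonds were cleaved, so no
  ## outer hydrogens; both bonds to the target were cleaved -> 2 junction H
  expect_identical(length(q$outer_h), 0L)
  expect_identical(length(q$junction_h), 2L)
  expect_identical(nrow(q$sys_cap_r_cap), n_chain)
  expect_identical(nrow(q$sys_l_cap_r_cap), n_chain + n_lig)
  n_res2 <- nrow(residue_atoms(cx, "A", 2))
  expect_identical(nrow(q$sys_concap), n_chain - n_res2 + 2L)
  ## concap contains no target-residue source atom, and no ligand atom
  expect_false(any(q$sys_concap$resno == 2 & q$sys_concap$role == "source"))
  expect_false(any(q$sys_concap$ligand))
  expect_false(any(q$sys_cap_r_cap$ligand))
})

test_that("junction hydrogens sit on the former bond vector at spec length", {
  g <- generate_complex(fixture_spec(
    n_residues = 5, ligand_atoms = 3,
    placements = data.frame(residue = 3, distance = 3.0), seed = 13))
  spec <- cap_spec(ch_bond_length = 1.09, nh_bond_length = 1.01)
  q <- build_quartet(g$complex, "A", 3, spec)
  expect_identical(length(q$junction_h), 2L)
  expect_identical(length(q$outer_h), 2L)
  hs <- q$sys_concap[q$sys_concap$role == "junction", ]
  ## H on C(i-1) at the C-H length, H on N(i+1) at the N-H length
  c_prev <- residue_atoms(g$complex, "A", 2)
  c_at <- c_prev[c_prev$name == "C", ]
  n_next <- residue_atoms(g$complex, "A", 4)
  n_at <- n_next[n_next$name == "N", ]
  d_ch <- min(sqrt((hs$x - c_at$x)^2 + (hs$y - c_at$y)^2 + (hs$z - c_at$z)^2))
  d_nh <- min(sqrt((hs$x - n_at$x)^2 + (hs$y - n_at$y)^2 + (hs$z - n_at$z)^2))
  expect_equal(d_ch, 1.09, tolerance = 1e-9)
  expect_equal(d_nh, 1.01, tolerance = 1e-9)
  ## collinearity with the former bond: H lies on the C(i-1)->N(i) segment
  r_target <- residue_atoms(g$complex, "A", 3)
  n_i <- r_target[r_target$name == "N", ]
  h1 <- hs[which.min(sqrt((hs$x - c_at$x)^2 + (hs$y - c_at$y)^2 +
                            (hs$z - c_at$z)^2)), ]
  v_bond <- c(n_i$x - c_at$x, n_i$y - c_at$y, n_i$z - c_at$z)
  v_h <- c(h1$x - c_at$x, h1$y - c_at$y, h1$z - c_at$z)
  cosang <- sum(v_bond * v_h) / sqrt(sum(v_bond^2) * sum(v_h^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
})

test_that("terminal residues are capped on one side only", {
  g <- three_residue_complex()
  q1 <- build_quartet(g$complex, "A", 1)
  expect_identical(length(q1$junction_h), 1L)
  ## concap = residue 2 + its junction hydrogen + the outer hydrogen that
  ## terminates residue 2's cleaved bond to residue 3
  expect_identical(length(q1$outer_h), 1L)
  n_res2 <- nrow(residue_atoms(g$complex, "A", 2))
  expect_identical(nrow(q1$sys_concap), n_res2 + 2L)
  expect_true(all(q1$sys_concap$resno == 2))
  q3 <- build_quartet(g$complex, "A", 3)
  expect_identical(length(q3$junction_h), 1L)
  expect_true(all(q3$sys_concap$resno == 2))
})

test_that("fragmentation refuses the ligand and unfragmentable targets", {
  g <- three_residue_complex()
  expect_error(build_quartet(g$complex, "B", 1), "ligand")
  expect_error(build_quartet(g$complex, "A", 9), "no polymer residue")
})

test_that("shared atoms keep identical source coordinates across systems", {
  g <- generate_complex(fixture_spec(
    n_residues = 5, ligand_atoms = 4,
    placements = data.frame(residue = 2, distance = 2.5), seed = 17,
    side_chain = TRUE))
  q <- build_quartet(g$complex, "A", 3)
  ## ligand-removed systems equal their ligand-free counterparts exactly
  strip <- function(sys) {
    out <- sys[!sys$ligand, c("serial", "x", "y", "z")]
    rownames(out) <- NULL
    out
  }
  expect_identical(strip(q$sys_l_cap_r_cap), strip(q$sys_cap_r_cap))
  expect_identical(strip(q$sys_l_concap), strip(q$sys_concap))
  ## all source atoms retain the complex's coordinates unchanged
  src <- q$sys_cap_r_cap[q$sys_cap_r_cap$role == "source", ]
  orig <- g$complex$atoms[match(src$serial, g$complex$atoms$serial), ]
  expect_identical(src$x, orig$x)
  expect_identical(src$y, orig$y)
  expect_identical(src$z, orig$z)
  ## side chains ride along with the caps
  expect_true("CB" %in% q$sys_concap$name)
})

test_that("four-term assembly is plain arithmetic over backend energies", {
  g <- three_residue_complex()
  q <- build_quartet(g$complex, "A", 2)
  expect_equal(mfcc_interaction_energy(q, replay_backend(
    c(-100, -60, -55, -15)), 10), 0, tolerance = 1e-12)
  expect_equal(mfcc_interaction_energy(q, replay_backend(
    c(-10, -4, -7, -2)), 10), -1, tolerance = 1e-12)
  failing <- energy_backend(function(sys, eps) stop("boom"), "failing")
  expect_error(mfcc_interaction_energy(q, failing, 10),
               "failed on system 'ligand\\+cap-R-cap'")
})

test_that("cap cancellation reduces MFCC to the direct pair energy", {
  ## with ghosted junction hydrogens the four-term assembly equals the
  ## brute-force ligand-residue pair sum
  for (seed in c(3, 8)) {
    g <- generate_complex(fixture_spec(
      n_residues = 4, ligand_atoms = 5,
      placements = data.frame(residue = 2, distance = 2.4), seed = seed))
    lig <- ligand_atoms(g$complex)
    for (resno in 1:4) {
      q <- build_quartet(g$complex, "A", resno)
      e_mfcc <- mfcc_interaction_energy(q, ghost_backend(), 10)
      e_pair <- pairsum(lig, residue_atoms(g$complex, "A", resno), 10)
      expect_lt(abs(e_mfcc - e_pair), 1e-8)
    }
  }
})
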