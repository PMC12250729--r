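## Shared fixture builders.  All fixtures are generated in code; nothing
## is read from disk unless a test writes it first.

## canonical three-residue complex with staggered ligand-residue contacts
three_residue_complex <- function(seed = 7, charge_scheme = "random",
                                  lj_scheme = "amber_like") {
  generate_complex(fixture_spec(
    n_residues = 3, ligand_atoms = 4,
    placements = data.frame(residue = c(1, 2, 3),
                            distance = c(2.1, 3.4, 5.9)),
    charge_scheme = charge_scheme, lj_scheme = lj_scheme, seed = seed))
}

## minimal two-atom system for hand-checked energies
two_atom_system <- function(q1, q2, r, eps = c(0, 0), rmin2 = c(0, 0)) {
  data.frame(serial = 1:2, name = c("X1", "X2"), elem = c("C", "C"),
             x = c(0, r), y = 0, z = 0,
             charge = c(q1, q2), eps = eps, rmin2 = rmin2,
             chain = "A", resno = 1:2, resid = "UNK",
             ligand = FALSE, role = "source",
             stringsAsFactors = FALSE)
}

## a backend that replays a fixed sequence of energies (for arithmetic
## checks of the four-term assembly)
replay_backend <- function(values) {
  i <- 0L
  energy_backend(function(system, dielectric) {
    i <<- i + 1L
    values[i]
  }, label = "replay")
}

ghost_backend <- function() classical_backend(exclude_junction = TRUE)
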