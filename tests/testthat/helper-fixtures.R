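# Shared synthetic fixtures. Lattices are small cells (hundreds of nm) of
# the canonical 0.4-um-diameter tube; full-cell geometry is exercised only
# where the copy-number arithmetic itself is under test.

tube_lattice <- function(cell_length = 900, helix_angle = 0, noise_sigma = 0,
                         seed = 1, ...) {
  generate_cylinder_lattice(lattice_spec(
    cell_length = cell_length, helix_angle = helix_angle,
    noise_sigma = noise_sigma, seed = seed, ...))
}

rad2deg_test <- function(x) x * 180 / pi

# memoised fixtures (graph building dominates suite run time)
.fixture_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}
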