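#!/usr/bin/env Rscript
# Simulate the study system: a hexagonally tiled S-layer tube with the
# canonical cell geometry (0.4-um diameter, 7-um length, 15-nm unit
# distance), plus a shorter noisy "imaging segment" used by the
# downstream lattice analyses, and the concentric envelope layers.

suppressPackageStartupMessages(library(slayermap))
dir.create("results", showWarnings = FALSE)

# full-size cell: the geometric reference for the census
full <- generate_cylinder_lattice(lattice_spec(seed = 1))
cat(sprintf("full cell tube: %d hexamer positions (%d rings x %d axial repeats)\n",
            nrow(full), length(unique(full$truth_ring_index)),
            max(table(full$truth_ring_index))))
write_particles(full, "results/full_cell.star", pixel_size = 10,
                truth_path = "results/full_cell_truth.tsv")

# imaging segment: 1.2 um of tube with 0.5-nm positional noise and a
# 2.83-degree helical offset of direction-1, as measured on real cells
seg <- generate_cylinder_lattice(
  lattice_spec(cell_length = 1200, helix_angle = 2.83, noise_sigma = 0.5,
               seed = 2),
  cell_id = "segment_001")
cat(sprintf("imaging segment: %d particles at sigma = 0.5 nm\n", nrow(seg)))
write_particles(seg, "results/segment.star", pixel_size = 10,
                truth_path = "results/segment_truth.tsv")

# the same segment with five lattice vacancies, for defect detection
segd <- add_defects(generate_cylinder_lattice(
  lattice_spec(cell_length = 1200, seed = 3), cell_id = "segment_defects"),
  n_vacancies = 5, seed = 4)
write_particles(segd, "results/segment_defects.star", pixel_size = 10,
                truth_path = "results/segment_defects_truth.tsv")
cat(sprintf("defect segment: %d particles, %d marked vacancy neighbours\n",
            nrow(segd), sum(segd$truth_near_vacancy)))

# envelope layers: membrane / S-layer base / S-layer cap / sheath
env <- generate_envelope_layers(envelope_spec(noise_sigma = 0.5, seed = 5))
write.table(env, "results/envelope_layers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gaps <- layer_spacing(env)$gaps
cat(sprintf("envelope spacings: PS-1 %.2f nm | S-layer height %.2f nm | PS-2 %.2f nm\n",
            gaps[["ps1"]], gaps[["slayer_height"]], gaps[["ps2"]]))
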