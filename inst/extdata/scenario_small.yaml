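# Small pre-generated synthetic scenario: regenerate with
#   scn <- simulateScenario(seed = 421, config = yaml::read_yaml(this_file))
# Seeded generators make the regenerated scenario identical to the one the
# tests use.
seed: 421
n_rows: 60
n_cols: 60
n_layers: 6
autocorr_range: 5
n_species: 3
marginality_targets: [1.0, 1.2, 1.5]
tolerance_target: 0.5
n_museum: 120
clustering: 0.0
n_classes: 4
patch_scale: 8
subcell_ratio: 4
n_sites: 25
points_per_site: 30
min_point_spacing: 0.2
detection_prob: 0.8
suitable_classes: [1]
suitable_fraction: 0.5
threshold_rule: kappa
pseudoabsence_threshold: 20
buffer_radius: 1.0
n_regions: 4
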