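# Demonstration run: one fully simulated comparison, small enough to finish
# in seconds. All randomness derives from `seed`.
output_dir: synmapr_demo_run
seed: 42
cascade:
  e_strict: 1.0e-10
  e_primary: 1.0e-6
  hsp_merge_window: 50000
comparisons:
  demo_map_vs_reference:
    simulation:
      n_chromosomes: 3
      markers_per_chromosome: 20
      mean_gap_bp: 500000
      n_events_per_lineage: 2
      marker_loss_rate: 0.05
      paralog_rate: 0.05
      n_spurious_multihit: 2
      cM_per_Mb_mean: 2
      cM_per_Mb_sd: 0.5
    synteny:
      min_markers: 3
      max_gap_target_bp: 3200000
      max_gap_query_cM: 12
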