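# Demo pipeline configuration: a small synthetic domain around two
# Ionian release sites, one simulated year, 50 larvae per spawning day.
out_dir: demo_out
seed: 42
stages:
  synth_field:
    lon_min: 18.8
    lon_max: 20.6
    lat_min: 39.3
    lat_max: 40.9
    d_lon: 0.0222222
    d_lat: 0.0222222
    depth_levels: [0, 10, 20]
    time_origin: "2004-01-01"
    n_days: 365
    gyre_strength: 0.15
    mean_temp_winter: 13
    mean_temp_summer: 26
    temp_peak_day: 225
  dispersal:
    site_subset: [OTH, KAP]
    config:
      particles_per_day: 50
      years: [2004]
      dt_minutes: 30
      pld_mean: 20
      pld_sd: 3
  synth_genotypes:
    n_loci: 200
    n_pops: 4
    sample_sizes: [20, 20, 20, 20]
    target_fst: 0.02
  popgen:
    n_perm: 199
  forward_sim:
    scenario: power
    n_demes: 4
    N: 400
    n_loci: 200
    t: 2
    replicates: 50
    sample_sizes: 25
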