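# Demonstration pipeline configuration: a small simulated study with a
# Pacific-style training set (marine and freshwater reference populations)
# and three query regions carrying a gradient of freshwater-haplotype
# frequencies. Problem sizes are kept small so the demo runs in seconds.
seed: 7
simulate:
  n_loci_neutral: 1600
  genome:
    chr1: 10000000
    chr2: 10000000
  depth_mean: 20
  base_error: 0.005
  missing_rate: 0.02
  populations:
    - {name: PAC-MAR1, region: Pacific, habitat: marine,     latitude: 61, n_individuals: 8, fst_drift: 0.02, freshwater_hap_freq: 0.0, inbreeding_f: 0.03}
    - {name: PAC-MAR2, region: Pacific, habitat: marine,     latitude: 60, n_individuals: 8, fst_drift: 0.02, freshwater_hap_freq: 0.0, inbreeding_f: 0.03}
    - {name: PAC-FW1,  region: Pacific, habitat: freshwater, latitude: 61, n_individuals: 8, fst_drift: 0.05, freshwater_hap_freq: 1.0, inbreeding_f: 0.05}
    - {name: PAC-FW2,  region: Pacific, habitat: freshwater, latitude: 61, n_individuals: 8, fst_drift: 0.05, freshwater_hap_freq: 1.0, inbreeding_f: 0.05}
    - {name: NOR-FW1,  region: North,   habitat: freshwater, latitude: 63, n_individuals: 8, fst_drift: 0.05, freshwater_hap_freq: 0.2, inbreeding_f: 0.05}
    - {name: NOR-FW2,  region: North,   habitat: freshwater, latitude: 65, n_individuals: 8, fst_drift: 0.05, freshwater_hap_freq: 0.3, inbreeding_f: 0.05}
    - {name: NOR-MAR1, region: North,   habitat: marine,     latitude: 64, n_individuals: 8, fst_drift: 0.03, freshwater_hap_freq: 0.05, inbreeding_f: 0.03}
    - {name: IBE-FW1,  region: Iberia,  habitat: freshwater, latitude: 40, n_individuals: 8, fst_drift: 0.10, freshwater_hap_freq: 0.9, inbreeding_f: 0.15}
    - {name: IBE-FW2,  region: Iberia,  habitat: freshwater, latitude: 41, n_individuals: 8, fst_drift: 0.10, freshwater_hap_freq: 0.8, inbreeding_f: 0.10}
    - {name: ADR-FW1,  region: Adriatic, habitat: freshwater, latitude: 45, n_individuals: 8, fst_drift: 0.08, freshwater_hap_freq: 0.6, inbreeding_f: 0.10}
    - {name: ADR-FW2,  region: Adriatic, habitat: freshwater, latitude: 44, n_individuals: 8, fst_drift: 0.08, freshwater_hap_freq: 0.5, inbreeding_f: 0.05}
  clusters:
    - {id: cl1, chrom: chr1, start: 1000000, end: 1400000, n_loci: 25}
    - {id: cl2, chrom: chr1, start: 4000000, end: 4300000, n_loci: 20}
    - {id: cl3, chrom: chr2, start: 2000000, end: 2500000, n_loci: 25}
    - {id: cl4, chrom: chr2, start: 6000000, end: 6300000, n_loci: 20}
training:
  marine: [PAC-MAR1, PAC-MAR2]
  freshwater: [PAC-FW1, PAC-FW2]
filter:
  max_missing_frac: 0.25
  min_gq: 20
  maf_min: 0.01
pca_method: both
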