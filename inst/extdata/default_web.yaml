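# Default synthetic scenario: a cold-water coral reef-like web with one
# suspended particulate organic matter source and three consumer guilds
# (suspension feeders, predators/detritivores, sponges) at the mean
# trophic positions observed for those guilds.
sources:
  - label: SPOM
    d13C: -21.9
    d15N: 4.2
    sd_d13C: 0.45
    sd_d15N: 1.6
guilds:
  - label: suspension_feeders
    trophic_level: 3.5
    n_taxa: 14
    offset_sd_d13C: 0.5
    offset_sd_d15N: 0.5
    source: 1
  - label: predators_detritivores
    trophic_level: 4.2
    n_taxa: 4
    offset_sd_d13C: 0.5
    offset_sd_d15N: 0.5
    source: 1
  - label: sponges
    trophic_level: 5.7
    n_taxa: 5
    offset_sd_d13C: 0.5
    offset_sd_d15N: 0.5
    source: 1
tef:
  tef_n: 3.4
  tef_c: 1.0
replicate_sd:
  d13C: 0.2
  d15N: 0.5
replicates_per_taxon: 3
replicates_per_source: 20
seed: 1
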