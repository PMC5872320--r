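# Fixture manifest: ten-plant Canary Islands Artemisia thuscula isolation survey
# (transcribed printed tables plus the metadata needed to rebuild records).
frame_totals:            # fragments plated per plant on PDA; derived from the
  LP1: 29                # CF granularity of each plant's printed values
  LP2: 38                # (3.45 = 1/29, 2.63 = 1/38, 5.00 = 1/20, 12.5 = 1/8)
  LP4: 20
  TF1: 8
  TF2: 8
  TF3: 8
  TF4: 8
  TF5: 8
  TF7: 8
  TF8: 8
case_study:              # per-plant case study (three media, two stem ages)
  per_medium: 8          # 12.5 = 1/8
  per_stem_age: 12       # 8.33 = 1/12
  per_plant: 24          # 4.17 = 1/24
printed_summaries:
  table4_avg: 50.78
  table4_sd: 16.13       # does not match recomputation from the printed
                         # column under either SD estimator; expected mismatch
  table6_denominator: 155  # implied by 0.65 = 1/155; inconsistent with the
                           # sum of the per-plant totals above (143)
  zero_similarity_cases: 27  # printed census; the printed species lists give 14
species_normalization:   # orthographic variants unified across tables
  "Neofusicoccum austral": "Neofusicoccum australe"
  "Paraphoma cf. chrysantemicola": "Paraphoma chrysantemicola"
non_reconstructable:
  table5_rows:
    - {plant_id: TF1, species: "Thielavia sp. 1", reason: "CF 8.33 is not an
        integer count over 8 fragments"}
    - {plant_id: LP1, species: "Aspergillus flavus", reason: "printed twice
        (3.45, 6.90); records merge them into one species with count 3"}
  cr_plants:
    - {plant_id: TF1, reason: "CR 62.5 implies 5 colonized fragments but the
        printed species rows account for at most 3"}
  tables: [table6, table8, table9]   # no record-level reconstruction possible
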