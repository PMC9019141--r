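# Default simulation conditions: the study population structure.
# Read with read_sim_config(); keys mirror sim_config() arguments.
n_individuals: 125
prop_female: 0.536        # 67 of 125 adults
prop_fed: 0.3654          # 38 supplemented of 104 broods
n_years: 4
start_year: 2009
habitat_mean: 0.25
habitat_sd: 0.18
clutch_mean_fed: 3.65
clutch_mean_control: 3.28
mass_mean:
  F: 158.5
  M: 152.8
mass_sd: 8.0
age_probs: [0.35, 0.2, 0.15, 0.1, 0.08, 0.06, 0.04, 0.02]
seed: 1
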