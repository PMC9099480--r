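# Base-case configuration: five-state daily-cycle model, 180-day horizon.
# Arms are calibrated to the trial's per-state life days and 180-day
# mortality (321 intervention / 324 control patients).
horizon: 180
extrapolation_horizon: 365
wtp_per_life_year: 100000
threshold_mode: nutrition-only
seeds:
  calibration: 20220401
  psa: 20220402
  trial: 20220403
costs:
  nutrition_inpatient_per_day: 5
  nutrition_outpatient_per_day: 5
  ward_per_day: 1650
  icu_per_day: 4654
  complication_per_day: 1513
  outpatient_fraction: 0.2
utility_weights:
  WARD: 0.002
  COMPLICATION: 0.002
  ICU: 0.002
  DISCHARGED: 0.002
grids:
  supplement_cost: [5, 100, 1000]
  outpatient_fraction: [0.2, 0.5, 1.0]
psa:
  n_draws: 1000
arms:
  intervention:
    targets:
      life_days:
        WARD: 123.84
        COMPLICATION: 10.09
        ICU: 1.88
        DISCHARGED: 18.77
      dead_fraction: 0.264797507788162   # 85 / 321
  control:
    targets:
      life_days:
        WARD: 111.24
        COMPLICATION: 14.20
        ICU: 1.90
        DISCHARGED: 21.47
      dead_fraction: 0.314814814814815   # 102 / 324
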