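# Default scenario configuration (all monetary values 2010 US$).
world:
  n_countries: 3
  cells_per_country: 20
  n_crops: 7
years:
  start: 2010
  end: 2030
yield_avg_window: 5          # trailing mean of annual yield anchors, years
spinup:
  threshold: 0.004           # max relative change between iterations
  max_iter: 40
demand:
  history_years: 40
  noise_sd: 0.08
  convergence_on: false
  convergence_rate: 1.0
market:
  lambda: 0.05               # exponential price adjustment rate; must sit
                             # inside the stability region of the
                             # settlement map (see the methods vignette)
  stocks_to_use: 0.2         # initial stock as fraction of annual use
  prices_from_baseline: true # re-anchor prices to baseline average costs
                             # after spin-up (configured prices otherwise)
  prices:                    # initial world prices, $/t
    cereals: 200
    oil_crops: 450
    pulses: 400
    starchy_roots: 150
    ruminant: 3000
    monogastric: 1800
    energy_crops: 120
surfaces:
  k_I: 2.0                   # irrigation blend shape
  g0: 0.5                    # management floor
  k_M: 2.0                   # management shape
  tech_rate: 0.002           # exogenous yield technology increment, /yr
costs: {}                    # overrides of default_costs(), e.g. fert_price
china_countries: []          # countries subject to the deforestation cap
ensemble:
  n: 8
  half_width: 0.5            # +-50% uniform parameter perturbation
seed: 1
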