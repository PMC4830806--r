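{
  "coefficients": {
    "a10": {"constant": 1.0},
    "a20": {"constant": 1.0},
    "a11": {"constant": 0.35, "harmonics": [{"amp": 0.05, "freq": 1.7320508075688772, "phase": 0.0, "waveform": "cos"}]},
    "a22": {"constant": 0.35, "harmonics": [{"amp": 0.05, "freq": 1.7320508075688772, "phase": 0.0, "waveform": "cos"}]},
    "a12": {"constant": 0.0001},
    "a21": {"constant": 0.0001},
    "m1": {"constant": 2.0},
    "m2": {"constant": 2.0},
    "c1": {"constant": 0.30005, "harmonics": [{"amp": 0.00005, "freq": 1.4142135623730951, "phase": 0.0, "waveform": "sin"}]},
    "c2": {"constant": 0.30005, "harmonics": [{"amp": 0.00005, "freq": 1.4142135623730951, "phase": 0.0, "waveform": "cos"}]}
  },
  "delays": {"tau10": 0.0001, "tau11": 0.0001, "tau12": 0.0002,
             "tau20": 0.0001, "tau21": 0.0002, "tau22": 0.0001},
  "schedule": {"base_period": 5, "jitter_amplitude": 0, "jitter_frequency": 0,
               "h1": 0.5, "h2": 0.4},
  "horizon": [0, 200],
  "initial_history": {"x1": 0.12, "x2": 0.02},
  "simulation": {"step": 0.01, "space": "log"},
  "analysis": {"fraction": 0.25},
  "seed": 1
}
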