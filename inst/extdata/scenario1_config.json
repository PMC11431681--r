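{
  "network": {
    "scenario": "s1",
    "n": 100,
    "connect_prob": 0.5,
    "natural_length": 10,
    "stiffness": 10
  },
  "protocol": {
    "n_resets": 200,
    "learning_rate": 0.02
  },
  "dynamics": {
    "damping": 1,
    "step_size": 0.01
  },
  "seed": 1
}
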