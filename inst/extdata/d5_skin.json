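{
  "chemical": {
    "name": "D5",
    "Ds": 1.46e-16,
    "Koa": 8570000,
    "Ksa": 32700,
    "Kls": 265
  },
  "surface": {
    "Ls": 1e-06,
    "A": 2.28,
    "Cs0": 88000000000,
    "n_layers": 10
  },
  "room": {
    "V": 670,
    "Q": 0.93,
    "Cout": 0,
    "Ca0": 0,
    "h": 0.0009
  },
  "simulation": {
    "mode": "stage2_only",
    "t_end": 7200,
    "output_interval": 10
  }
}
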