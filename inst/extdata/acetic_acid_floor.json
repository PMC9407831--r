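{
  "chemical": {
    "name": "acetic acid",
    "Ds": 5.05e-10,
    "Koa": 166000,
    "Ksa": 627,
    "Kls": 265
  },
  "surface": {
    "Ls": 0.019,
    "A": 0.56,
    "Cs0": 0,
    "n_layers": 10
  },
  "room": {
    "V": 24.5,
    "Q": 0.00833,
    "Cout": 0,
    "Ca0": 0,
    "h": 0.0009
  },
  "simulation": {
    "mode": "full",
    "t_end": 43200,
    "output_interval": 60
  },
  "liquid": {
    "Cl": 42000000000,
    "m0": 2520000
  }
}
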