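[
  {
    "label": "G0",
    "radius": 15,
    "opening_degree": 0,
    "free_edge_shape": "linear"
  },
  {
    "label": "G1",
    "radius": 15,
    "opening_degree": 20,
    "free_edge_shape": "convex"
  },
  {
    "label": "G2",
    "radius": 15,
    "opening_degree": 20,
    "free_edge_shape": "concave"
  },
  {
    "label": "G3",
    "radius": 15,
    "opening_degree": 25,
    "free_edge_shape": "linear"
  },
  {
    "label": "G4",
    "radius": 15,
    "opening_degree": 25,
    "free_edge_shape": "concave"
  },
  {
    "label": "G5",
    "radius": 15,
    "opening_degree": 30,
    "free_edge_shape": "linear"
  },
  {
    "label": "G6",
    "radius": 15,
    "opening_degree": 50,
    "free_edge_shape": "linear"
  }
]
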