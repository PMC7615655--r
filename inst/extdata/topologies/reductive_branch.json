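{
  "name": "reductive_branch",
  "entry": "PYR",
  "pools": ["PYR", "OAA", "MAL", "FUM", "SUC"],
  "co2_policy": {
    "recycle_fraction": 0
  },
  "reactions": [
    {
      "name": "PC",
      "substrates": "PYR",
      "products": "OAA",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3],
          [0, 1]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "MDHr",
      "substrates": "OAA",
      "products": "MAL",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3],
          [1, 4]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "FHr",
      "substrates": "MAL",
      "products": "FUM",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3],
          [1, 4]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": "FUM"
    },
    {
      "name": "FRD",
      "substrates": "FUM",
      "products": "SUC",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3],
          [1, 4]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": "SUC"
    }
  ]
}
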