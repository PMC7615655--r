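{
  "name": "oxidative_tca",
  "entry": "PYR",
  "pools": ["PYR", "ACA", "OAA", "CIT", "ICIT", "AKG", "SUC", "FUM", "MAL"],
  "co2_policy": {
    "recycle_fraction": 0
  },
  "reactions": [
    {
      "name": "PDH",
      "substrates": "PYR",
      "products": "ACA",
      "atom_map": [
        [
          [1, 2],
          [1, 3]
        ]
      ],
      "losses": [
        [1, 1]
      ],
      "loss_to": "co2",
      "symmetric_products": []
    },
    {
      "name": "CS",
      "substrates": ["OAA", "ACA"],
      "products": "CIT",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3],
          [1, 4],
          [2, 1],
          [2, 2]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "ACO",
      "substrates": "CIT",
      "products": "ICIT",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3],
          [1, 4],
          [1, 5],
          [1, 6]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "IDH",
      "substrates": "ICIT",
      "products": "AKG",
      "atom_map": [
        [
          [1, 4],
          [1, 3],
          [1, 2],
          [1, 5],
          [1, 6]
        ]
      ],
      "losses": [
        [1, 1]
      ],
      "loss_to": "co2",
      "symmetric_products": []
    },
    {
      "name": "AKGDH",
      "substrates": "AKG",
      "products": "SUC",
      "atom_map": [
        [
          [1, 2],
          [1, 3],
          [1, 4],
          [1, 5]
        ]
      ],
      "losses": [
        [1, 1]
      ],
      "loss_to": "co2",
      "symmetric_products": "SUC"
    },
    {
      "name": "SDH",
      "substrates": "SUC",
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
      "name": "FH",
      "substrates": "FUM",
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
      "name": "MDH",
      "substrates": "MAL",
      "products": "OAA",
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
    }
  ]
}
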