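{
  "name": "glycolysis",
  "entry": "GLC",
  "pools": ["GLC", "G6P", "F6P", "FBP", "DHAP", "GAP", "3PGA", "2PGA", "PEP", "PYR", "ACD", "ETH"],
  "co2_policy": {
    "recycle_fraction": 0
  },
  "reactions": [
    {
      "name": "HK",
      "substrates": "GLC",
      "products": "G6P",
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
      "name": "PGI",
      "substrates": "G6P",
      "products": "F6P",
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
      "name": "PFK",
      "substrates": "F6P",
      "products": "FBP",
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
      "name": "ALD",
      "substrates": "FBP",
      "products": ["DHAP", "GAP"],
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3]
        ],
        [
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
      "name": "TPI",
      "substrates": "DHAP",
      "products": "GAP",
      "atom_map": [
        [
          [1, 3],
          [1, 2],
          [1, 1]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "GAPDH",
      "substrates": "GAP",
      "products": "3PGA",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "PGM",
      "substrates": "3PGA",
      "products": "2PGA",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "ENO",
      "substrates": "2PGA",
      "products": "PEP",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "PK",
      "substrates": "PEP",
      "products": "PYR",
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [1, 3]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    },
    {
      "name": "PDC",
      "substrates": "PYR",
      "products": "ACD",
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
      "name": "ADH",
      "substrates": "ACD",
      "products": "ETH",
      "atom_map": [
        [
          [1, 1],
          [1, 2]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    }
  ]
}
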