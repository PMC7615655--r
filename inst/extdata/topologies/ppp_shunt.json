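{
  "name": "ppp_shunt",
  "entry": "G6P",
  "pools": ["G6P", "6PGA", "Ru5P", "F6P", "GAP"],
  "co2_policy": {
    "recycle_fraction": 0
  },
  "reactions": [
    {
      "name": "G6PDH",
      "substrates": "G6P",
      "products": "6PGA",
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
      "name": "6PGD",
      "substrates": "6PGA",
      "products": "Ru5P",
      "atom_map": [
        [
          [1, 2],
          [1, 3],
          [1, 4],
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
      "name": "TKTA",
      "substrates": ["Ru5P", "Ru5P", "Ru5P"],
      "products": ["F6P", "F6P", "GAP"],
      "atom_map": [
        [
          [1, 1],
          [1, 2],
          [2, 1],
          [1, 3],
          [1, 4],
          [1, 5]
        ],
        [
          [3, 1],
          [3, 2],
          [2, 2],
          [2, 3],
          [2, 4],
          [2, 5]
        ],
        [
          [3, 3],
          [3, 4],
          [3, 5]
        ]
      ],
      "losses": [],
      "loss_to": [],
      "symmetric_products": []
    }
  ]
}
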