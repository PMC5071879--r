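{
  "schema": "dysonspec-wf-1",
  "basis": {
    "mo_set_id": "cas-example",
    "n_spatial": 3
  },
  "states": {
    "S0": {
      "n_electrons": 4,
      "multiplicity": 1,
      "energy": 0,
      "terms": [
        {
          "occ": [1, 2, 4, 5],
          "coef": 0.98
        },
        {
          "occ": [1, 3, 4, 6],
          "coef": 0.198997487421324
        }
      ]
    },
    "D0": {
      "n_electrons": 3,
      "multiplicity": 2,
      "energy": 8.6,
      "terms": [
        {
          "occ": [1, 2, 4],
          "coef": -0.265548017443219
        },
        {
          "occ": [1, 2, 5],
          "coef": 0.0778447186809664
        },
        {
          "occ": [1, 2, 6],
          "coef": -0.354215294949472
        },
        {
          "occ": [1, 3, 4],
          "coef": 0.676224882040282
        },
        {
          "occ": [1, 3, 5],
          "coef": 0.139675318494776
        },
        {
          "occ": [1, 3, 6],
          "coef": -0.34778901339782
        },
        {
          "occ": [2, 3, 4],
          "coef": 0.206616699103854
        },
        {
          "occ": [2, 3, 5],
          "coef": 0.312969062226768
        },
        {
          "occ": [2, 3, 6],
          "coef": 0.244068427377243
        }
      ]
    },
    "D1": {
      "n_electrons": 3,
      "multiplicity": 2,
      "energy": 9.4,
      "terms": [
        {
          "occ": [1, 2, 4],
          "coef": -0.173932306468332
        },
        {
          "occ": [1, 2, 5],
          "coef": 0.518172823694023
        },
        {
          "occ": [1, 2, 6],
          "coef": 0.0298570739876771
        },
        {
          "occ": [1, 3, 4],
          "coef": -0.0165960203975324
        },
        {
          "occ": [1, 3, 5],
          "coef": -0.688765401785375
        },
        {
          "occ": [1, 3, 6],
          "coef": 0.273101227828586
        },
        {
          "occ": [2, 3, 4],
          "coef": 0.0425205256903855
        },
        {
          "occ": [2, 3, 5],
          "coef": 0.0814462602711914
        },
        {
          "occ": [2, 3, 6],
          "coef": 0.377695720171977
        }
      ]
    }
  }
}
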