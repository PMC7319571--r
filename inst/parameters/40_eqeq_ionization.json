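{
  "format_version": "1.0",
  "id": "eqeq-ionization",
  "method": "eqeq",
  "citation": "chi = (IP+EA)/2 and J = IP-EA from experimental first ionization energies and electron affinities (CRC tables), per Wilmer, Kim & Snurr (2012) J Phys Chem Lett 3:2506",
  "scheme": "plain",
  "common": {
    "lambda": 1.2
  },
  "atom": [
    {
      "element": "H",
      "value": "*",
      "params": {
        "chi": 7.1761,
        "J": 12.8438
      }
    },
    {
      "element": "B",
      "value": "*",
      "params": {
        "chi": 4.28886,
        "J": 8.01828
      }
    },
    {
      "element": "C",
      "value": "*",
      "params": {
        "chi": 6.26106,
        "J": 9.99788
      }
    },
    {
      "element": "N",
      "value": "*",
      "params": {
        "chi": 7.232,
        "J": 14.604
      }
    },
    {
      "element": "O",
      "value": "*",
      "params": {
        "chi": 7.539555,
        "J": 12.15689
      }
    },
    {
      "element": "F",
      "value": "*",
      "params": {
        "chi": 10.411595,
        "J": 14.02081
      }
    },
    {
      "element": "Na",
      "value": "*",
      "params": {
        "chi": 2.843465,
        "J": 4.59107
      }
    },
    {
      "element": "Mg",
      "value": "*",
      "params": {
        "chi": 3.823,
        "J": 7.646
      }
    },
    {
      "element": "Al",
      "value": "*",
      "params": {
        "chi": 3.209415,
        "J": 5.55317
      }
    },
    {
      "element": "Si",
      "value": "*",
      "params": {
        "chi": 4.77026,
        "J": 6.76148
      }
    },
    {
      "element": "P",
      "value": "*",
      "params": {
        "chi": 5.60225,
        "J": 9.7115
      }
    },
    {
      "element": "S",
      "value": "*",
      "params": {
        "chi": 6.21855,
        "J": 8.2829
      }
    },
    {
      "element": "Cl",
      "value": "*",
      "params": {
        "chi": 8.28986,
        "J": 9.35428
      }
    },
    {
      "element": "K",
      "value": "*",
      "params": {
        "chi": 2.42123,
        "J": 3.83954
      }
    },
    {
      "element": "Ca",
      "value": "*",
      "params": {
        "chi": 3.068775,
        "J": 6.08845
      }
    },
    {
      "element": "Zn",
      "value": "*",
      "params": {
        "chi": 4.697,
        "J": 9.394
      }
    },
    {
      "element": "Br",
      "value": "*",
      "params": {
        "chi": 7.588795,
        "J": 8.45041
      }
    },
    {
      "element": "I",
      "value": "*",
      "params": {
        "chi": 6.75502,
        "J": 7.39196
      }
    }
  ]
}
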