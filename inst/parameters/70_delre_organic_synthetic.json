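{
  "format_version": "1.0",
  "id": "delre-organic-synthetic",
  "method": "delre",
  "citation": "synthetic demonstration parameters in the style of Del Re (1958) J Chem Soc 4031",
  "scheme": "plain",
  "note": "SYNTHETIC: magnitudes chosen for plausibility, not fitted",
  "common": [],
  "atom": [
    {
      "element": "H",
      "value": "*",
      "params": {
        "delta0": 0
      }
    },
    {
      "element": "C",
      "value": "*",
      "params": {
        "delta0": 0.07
      }
    },
    {
      "element": "N",
      "value": "*",
      "params": {
        "delta0": 0.24
      }
    },
    {
      "element": "O",
      "value": "*",
      "params": {
        "delta0": 0.4
      }
    },
    {
      "element": "S",
      "value": "*",
      "params": {
        "delta0": 0.07
      }
    },
    {
      "element": "Cl",
      "value": "*",
      "params": {
        "delta0": 0.35
      }
    }
  ],
  "bond": [
    {
      "elements": ["C", "H"],
      "order": 1,
      "params": {
        "gamma1": 0.3,
        "gamma2": 0.4,
        "epsilon": 1
      }
    },
    {
      "elements": ["C", "C"],
      "order": 1,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.1,
        "epsilon": 1
      }
    },
    {
      "elements": ["C", "C"],
      "order": 2,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.1,
        "epsilon": 0.9
      }
    },
    {
      "elements": ["C", "N"],
      "order": 1,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.3,
        "epsilon": 1
      }
    },
    {
      "elements": ["C", "N"],
      "order": 2,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.3,
        "epsilon": 0.9
      }
    },
    {
      "elements": ["C", "O"],
      "order": 1,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.3,
        "epsilon": 0.95
      }
    },
    {
      "elements": ["C", "O"],
      "order": 2,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.3,
        "epsilon": 0.85
      }
    },
    {
      "elements": ["O", "H"],
      "order": 1,
      "params": {
        "gamma1": 0.4,
        "gamma2": 0.45,
        "epsilon": 0.6
      }
    },
    {
      "elements": ["N", "H"],
      "order": 1,
      "params": {
        "gamma1": 0.35,
        "gamma2": 0.4,
        "epsilon": 0.7
      }
    },
    {
      "elements": ["N", "N"],
      "order": 1,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.1,
        "epsilon": 0.95
      }
    },
    {
      "elements": ["O", "O"],
      "order": 1,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.1,
        "epsilon": 0.95
      }
    },
    {
      "elements": ["C", "S"],
      "order": 1,
      "params": {
        "gamma1": 0.1,
        "gamma2": 0.2,
        "epsilon": 0.75
      }
    },
    {
      "elements": ["S", "H"],
      "order": 1,
      "params": {
        "gamma1": 0.2,
        "gamma2": 0.3,
        "epsilon": 0.7
      }
    },
    {
      "elements": ["C", "Cl"],
      "order": 1,
      "params": {
        "gamma1": 0.2,
        "gamma2": 0.35,
        "epsilon": 0.65
      }
    }
  ]
}
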