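{
  "format_version": "1.0",
  "id": "sfkeem-demo-synthetic",
  "method": "sfkeem",
  "citation": "synthetic demonstration parameters (A: Pauling electronegativities; B, sigma chosen for well-conditioned systems)",
  "scheme": "plain",
  "note": "SYNTHETIC: not a fitted literature set",
  "common": {
    "sigma": 0.5
  },
  "atom": [
    {
      "element": "H",
      "value": "*",
      "params": {
        "A": 2.2,
        "B": 0.9
      }
    },
    {
      "element": "C",
      "value": "*",
      "params": {
        "A": 2.55,
        "B": 0.65
      }
    },
    {
      "element": "N",
      "value": "*",
      "params": {
        "A": 3.04,
        "B": 0.7
      }
    },
    {
      "element": "O",
      "value": "*",
      "params": {
        "A": 3.44,
        "B": 0.8
      }
    },
    {
      "element": "F",
      "value": "*",
      "params": {
        "A": 3.98,
        "B": 1
      }
    },
    {
      "element": "P",
      "value": "*",
      "params": {
        "A": 2.19,
        "B": 0.55
      }
    },
    {
      "element": "S",
      "value": "*",
      "params": {
        "A": 2.58,
        "B": 0.6
      }
    },
    {
      "element": "Cl",
      "value": "*",
      "params": {
        "A": 3.16,
        "B": 0.75
      }
    },
    {
      "element": "Br",
      "value": "*",
      "params": {
        "A": 2.96,
        "B": 0.7
      }
    },
    {
      "element": "I",
      "value": "*",
      "params": {
        "A": 2.66,
        "B": 0.65
      }
    }
  ]
}
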