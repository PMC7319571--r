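{
  "format_version": "1.0",
  "id": "eem-bultinck2002",
  "method": "eem",
  "citation": "Bultinck et al. (2002) J Phys Chem A 106:7887; B3LYP/6-31G* Mulliken calibration",
  "scheme": "plain",
  "common": {
    "kappa": 0.529176
  },
  "atom": [
    {
      "element": "H",
      "value": "*",
      "params": {
        "A": 0.20606,
        "B": 1.31942
      }
    },
    {
      "element": "Li",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "B",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "C",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "N",
      "value": "*",
      "params": {
        "A": 0.49279,
        "B": 0.69038
      }
    },
    {
      "element": "O",
      "value": "*",
      "params": {
        "A": 0.73013,
        "B": 1.08856
      }
    },
    {
      "element": "F",
      "value": "*",
      "params": {
        "A": 0.72052,
        "B": 1.45328
      }
    },
    {
      "element": "Na",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "Mg",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "Si",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "P",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "S",
      "value": "*",
      "params": {
        "A": 0.6202,
        "B": 0.4128
      }
    },
    {
      "element": "Cl",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "K",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "Ca",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "Fe",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "Cu",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "Zn",
      "value": "*",
      "params": {
        "A": 0.36237,
        "B": 0.65932
      }
    },
    {
      "element": "Br",
      "value": "*",
      "params": {
        "A": 0.70052,
        "B": 1.09108
      }
    },
    {
      "element": "I",
      "value": "*",
      "params": {
        "A": 0.68052,
        "B": 0.61328
      }
    }
  ]
}
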