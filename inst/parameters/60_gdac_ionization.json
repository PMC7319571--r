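{
  "format_version": "1.0",
  "id": "gdac-ionization",
  "method": "gdac",
  "citation": "linear electronegativity chi(q) = a + b q with a = (IP+EA)/2, b = IP-EA from experimental ionization data, per Cho et al. (2001) J Phys Chem B 105:3624",
  "scheme": "plain",
  "common": [],
  "atom": [
    {
      "element": "H",
      "value": "*",
      "params": {
        "a": 7.1761,
        "b": 12.8438
      }
    },
    {
      "element": "C",
      "value": "*",
      "params": {
        "a": 6.26106,
        "b": 9.99788
      }
    },
    {
      "element": "N",
      "value": "*",
      "params": {
        "a": 7.232,
        "b": 14.604
      }
    },
    {
      "element": "O",
      "value": "*",
      "params": {
        "a": 7.539555,
        "b": 12.15689
      }
    },
    {
      "element": "F",
      "value": "*",
      "params": {
        "a": 10.411595,
        "b": 14.02081
      }
    },
    {
      "element": "P",
      "value": "*",
      "params": {
        "a": 5.60225,
        "b": 9.7115
      }
    },
    {
      "element": "S",
      "value": "*",
      "params": {
        "a": 6.21855,
        "b": 8.2829
      }
    },
    {
      "element": "Cl",
      "value": "*",
      "params": {
        "a": 8.28986,
        "b": 9.35428
      }
    },
    {
      "element": "Br",
      "value": "*",
      "params": {
        "a": 7.588795,
        "b": 8.45041
      }
    },
    {
      "element": "I",
      "value": "*",
      "params": {
        "a": 6.75502,
        "b": 7.39196
      }
    }
  ]
}
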