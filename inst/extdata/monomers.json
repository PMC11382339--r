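[
  {
    "code": "A",
    "name": "DNA adenine",
    "base_formula": "C5H5N5",
    "nucleoside_formula": "C10H13N5O3",
    "bridge_delta": ""
  },
  {
    "code": "lA",
    "name": "LNA adenine",
    "base_formula": "C5H5N5",
    "nucleoside_formula": "C10H13N5O3",
    "bridge_delta": "CH2O"
  },
  {
    "code": "eA",
    "name": "cEt adenine",
    "base_formula": "C5H5N5",
    "nucleoside_formula": "C10H13N5O3",
    "bridge_delta": "C2H4O"
  },
  {
    "code": "C",
    "name": "DNA cytosine",
    "base_formula": "C4H5N3O",
    "nucleoside_formula": "C9H13N3O4",
    "bridge_delta": ""
  },
  {
    "code": "lC",
    "name": "LNA cytosine",
    "base_formula": "C4H5N3O",
    "nucleoside_formula": "C9H13N3O4",
    "bridge_delta": "CH2O"
  },
  {
    "code": "eC",
    "name": "cEt cytosine",
    "base_formula": "C4H5N3O",
    "nucleoside_formula": "C9H13N3O4",
    "bridge_delta": "C2H4O"
  },
  {
    "code": "G",
    "name": "DNA guanine",
    "base_formula": "C5H5N5O",
    "nucleoside_formula": "C10H13N5O4",
    "bridge_delta": ""
  },
  {
    "code": "lG",
    "name": "LNA guanine",
    "base_formula": "C5H5N5O",
    "nucleoside_formula": "C10H13N5O4",
    "bridge_delta": "CH2O"
  },
  {
    "code": "eG",
    "name": "cEt guanine",
    "base_formula": "C5H5N5O",
    "nucleoside_formula": "C10H13N5O4",
    "bridge_delta": "C2H4O"
  },
  {
    "code": "T",
    "name": "DNA thymine",
    "base_formula": "C5H6N2O2",
    "nucleoside_formula": "C10H14N2O5",
    "bridge_delta": ""
  },
  {
    "code": "lT",
    "name": "LNA thymine",
    "base_formula": "C5H6N2O2",
    "nucleoside_formula": "C10H14N2O5",
    "bridge_delta": "CH2O"
  },
  {
    "code": "eT",
    "name": "cEt thymine",
    "base_formula": "C5H6N2O2",
    "nucleoside_formula": "C10H14N2O5",
    "bridge_delta": "C2H4O"
  },
  {
    "code": "mC",
    "name": "DNA 5-methylcytosine",
    "base_formula": "C5H7N3O",
    "nucleoside_formula": "C10H15N3O4",
    "bridge_delta": ""
  },
  {
    "code": "lmC",
    "name": "LNA 5-methylcytosine",
    "base_formula": "C5H7N3O",
    "nucleoside_formula": "C10H15N3O4",
    "bridge_delta": "CH2O"
  },
  {
    "code": "emC",
    "name": "cEt 5-methylcytosine",
    "base_formula": "C5H7N3O",
    "nucleoside_formula": "C10H15N3O4",
    "bridge_delta": "C2H4O"
  }
]
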