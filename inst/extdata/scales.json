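{
  "hydropathy": {
    "A": 1.8,
    "R": -4.5,
    "N": -3.5,
    "D": -3.5,
    "C": 2.5,
    "Q": -3.5,
    "E": -3.5,
    "G": -0.4,
    "H": -3.2,
    "I": 4.5,
    "L": 3.8,
    "K": -3.9,
    "M": 1.9,
    "F": 2.8,
    "P": -1.6,
    "S": -0.8,
    "T": -0.7,
    "W": -0.9,
    "Y": -1.3,
    "V": 4.2
  },
  "volume": {
    "A": 88.6,
    "R": 173.4,
    "N": 114.1,
    "D": 111.1,
    "C": 108.5,
    "Q": 143.8,
    "E": 138.4,
    "G": 60.1,
    "H": 153.2,
    "I": 166.7,
    "L": 166.7,
    "K": 168.6,
    "M": 162.9,
    "F": 189.9,
    "P": 112.7,
    "S": 89,
    "T": 116.1,
    "W": 227.8,
    "Y": 193.6,
    "V": 140
  },
  "helix": {
    "A": 1.42,
    "R": 0.98,
    "N": 0.67,
    "D": 1.01,
    "C": 0.7,
    "Q": 1.11,
    "E": 1.51,
    "G": 0.57,
    "H": 1,
    "I": 1.08,
    "L": 1.21,
    "K": 1.16,
    "M": 1.45,
    "F": 1.13,
    "P": 0.57,
    "S": 0.77,
    "T": 0.83,
    "W": 1.08,
    "Y": 0.69,
    "V": 1.06
  },
  "sheet": {
    "A": 0.83,
    "R": 0.93,
    "N": 0.89,
    "D": 0.54,
    "C": 1.19,
    "Q": 1.1,
    "E": 0.37,
    "G": 0.75,
    "H": 0.87,
    "I": 1.6,
    "L": 1.3,
    "K": 0.74,
    "M": 1.05,
    "F": 1.38,
    "P": 0.55,
    "S": 0.75,
    "T": 1.19,
    "W": 1.37,
    "Y": 1.47,
    "V": 1.7
  },
  "turn": {
    "A": 0.66,
    "R": 0.95,
    "N": 1.56,
    "D": 1.46,
    "C": 1.19,
    "Q": 0.98,
    "E": 0.74,
    "G": 1.56,
    "H": 0.95,
    "I": 0.47,
    "L": 0.59,
    "K": 1.01,
    "M": 0.6,
    "F": 0.6,
    "P": 1.52,
    "S": 1.43,
    "T": 0.96,
    "W": 0.96,
    "Y": 1.14,
    "V": 0.5
  },
  "frequency": {
    "A": 0.074,
    "R": 0.052,
    "N": 0.045,
    "D": 0.054,
    "C": 0.025,
    "Q": 0.034,
    "E": 0.054,
    "G": 0.074,
    "H": 0.026,
    "I": 0.068,
    "L": 0.099,
    "K": 0.058,
    "M": 0.025,
    "F": 0.047,
    "P": 0.039,
    "S": 0.057,
    "T": 0.051,
    "W": 0.013,
    "Y": 0.032,
    "V": 0.073
  },
  "max_asa": {
    "A": 129,
    "R": 274,
    "N": 195,
    "D": 193,
    "C": 167,
    "Q": 225,
    "E": 223,
    "G": 104,
    "H": 224,
    "I": 197,
    "L": 201,
    "K": 236,
    "M": 224,
    "F": 240,
    "P": 159,
    "S": 155,
    "T": 172,
    "W": 285,
    "Y": 263,
    "V": 174
  },
  "vdw_radii": {
    "C": 1.7,
    "N": 1.55,
    "O": 1.52,
    "S": 1.8,
    "H": 1.2,
    "P": 1.8
  }
}
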