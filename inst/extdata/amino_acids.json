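{
  "version": "1.0",
  "scales": ["hydrophobicity", "beta_propensity", "aromaticity"],
  "residues": [
    {
      "code": "A",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": 1.8,
        "beta_propensity": 0.83,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "C",
        "name": "CB",
        "hydrophobic": true,
        "donor": false,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "R",
      "net_side_chain_charge": 1,
      "scales": {
        "hydrophobicity": -4.5,
        "beta_propensity": 0.93,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "N",
        "name": "NH1",
        "hydrophobic": false,
        "donor": true,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 1
      }
    },
    {
      "code": "N",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -3.5,
        "beta_propensity": 0.89,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "O",
        "name": "OD1",
        "hydrophobic": false,
        "donor": true,
        "acceptor": true,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "D",
      "net_side_chain_charge": -1,
      "scales": {
        "hydrophobicity": -3.5,
        "beta_propensity": 0.54,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "O",
        "name": "OD1",
        "hydrophobic": false,
        "donor": false,
        "acceptor": true,
        "aromatic": false,
        "fcharge": -1
      }
    },
    {
      "code": "C",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": 2.5,
        "beta_propensity": 1.19,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "S",
        "name": "SG",
        "hydrophobic": true,
        "donor": true,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "Q",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -3.5,
        "beta_propensity": 1.1,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "O",
        "name": "OE1",
        "hydrophobic": false,
        "donor": true,
        "acceptor": true,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "E",
      "net_side_chain_charge": -1,
      "scales": {
        "hydrophobicity": -3.5,
        "beta_propensity": 0.37,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "O",
        "name": "OE1",
        "hydrophobic": false,
        "donor": false,
        "acceptor": true,
        "aromatic": false,
        "fcharge": -1
      }
    },
    {
      "code": "G",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -0.4,
        "beta_propensity": 0.75,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "C",
        "name": "CB",
        "hydrophobic": false,
        "donor": false,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "H",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -3.2,
        "beta_propensity": 0.87,
        "aromaticity": 1
      },
      "side_chain": {
        "element": "N",
        "name": "NE2",
        "hydrophobic": false,
        "donor": false,
        "acceptor": true,
        "aromatic": true,
        "fcharge": 0
      }
    },
    {
      "code": "I",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": 4.5,
        "beta_propensity": 1.6,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "C",
        "name": "CB",
        "hydrophobic": true,
        "donor": false,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "L",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": 3.8,
        "beta_propensity": 1.3,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "C",
        "name": "CB",
        "hydrophobic": true,
        "donor": false,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "K",
      "net_side_chain_charge": 1,
      "scales": {
        "hydrophobicity": -3.9,
        "beta_propensity": 0.74,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "N",
        "name": "NZ",
        "hydrophobic": false,
        "donor": true,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 1
      }
    },
    {
      "code": "M",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": 1.9,
        "beta_propensity": 1.05,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "S",
        "name": "SD",
        "hydrophobic": true,
        "donor": false,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "F",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": 2.8,
        "beta_propensity": 1.38,
        "aromaticity": 1
      },
      "side_chain": {
        "element": "C",
        "name": "CZ",
        "hydrophobic": true,
        "donor": false,
        "acceptor": false,
        "aromatic": true,
        "fcharge": 0
      }
    },
    {
      "code": "P",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -1.6,
        "beta_propensity": 0.55,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "C",
        "name": "CB",
        "hydrophobic": true,
        "donor": false,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "S",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -0.8,
        "beta_propensity": 0.75,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "O",
        "name": "OG",
        "hydrophobic": false,
        "donor": true,
        "acceptor": true,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "T",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -0.7,
        "beta_propensity": 1.19,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "O",
        "name": "OG1",
        "hydrophobic": false,
        "donor": true,
        "acceptor": true,
        "aromatic": false,
        "fcharge": 0
      }
    },
    {
      "code": "W",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -0.9,
        "beta_propensity": 1.37,
        "aromaticity": 1
      },
      "side_chain": {
        "element": "C",
        "name": "CZ2",
        "hydrophobic": true,
        "donor": true,
        "acceptor": false,
        "aromatic": true,
        "fcharge": 0
      }
    },
    {
      "code": "Y",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": -1.3,
        "beta_propensity": 1.47,
        "aromaticity": 1
      },
      "side_chain": {
        "element": "C",
        "name": "CZ",
        "hydrophobic": true,
        "donor": true,
        "acceptor": true,
        "aromatic": true,
        "fcharge": 0
      }
    },
    {
      "code": "V",
      "net_side_chain_charge": 0,
      "scales": {
        "hydrophobicity": 4.2,
        "beta_propensity": 1.7,
        "aromaticity": 0
      },
      "side_chain": {
        "element": "C",
        "name": "CB",
        "hydrophobic": true,
        "donor": false,
        "acceptor": false,
        "aromatic": false,
        "fcharge": 0
      }
    }
  ]
}
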