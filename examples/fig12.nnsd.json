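{
  "format_version": "1.0",
  "metadata": {
    "title": "Associative-memory hypercolumn"
  },
  "regions": [
    {
      "id": "cortex",
      "kind": "area",
      "name": "",
      "display_order": 1
    }
  ],
  "layers": [
    {
      "id": "cortex.II",
      "name": "II",
      "area": "cortex"
    },
    {
      "id": "cortex.III",
      "name": "III",
      "area": "cortex"
    }
  ],
  "populations": [
    {
      "id": "basket",
      "label": {
        "ephys": "FS",
        "morph": "NPYR"
      },
      "layer": "cortex.III",
      "region": "cortex"
    },
    {
      "id": "mc1_pyr",
      "label": {
        "ephys": "RS",
        "morph": "PYR"
      },
      "layer": "cortex.II",
      "region": "cortex"
    },
    {
      "id": "mc1_rsnp",
      "label": {
        "ephys": "RS",
        "morph": "NPYR"
      },
      "layer": "cortex.III",
      "region": "cortex"
    },
    {
      "id": "mc2_pyr",
      "label": {
        "ephys": "RS",
        "morph": "PYR"
      },
      "layer": "cortex.II",
      "region": "cortex"
    },
    {
      "id": "mc2_rsnp",
      "label": {
        "ephys": "RS",
        "morph": "NPYR"
      },
      "layer": "cortex.III",
      "region": "cortex"
    },
    {
      "id": "stim",
      "label": {
        "morph": "STIM"
      },
      "region": "cortex"
    }
  ],
  "projections": [
    {
      "id": "basket_pyr1",
      "source": "basket",
      "target": "mc1_pyr",
      "excitation": "inhibitory"
    },
    {
      "id": "basket_pyr2",
      "source": "basket",
      "target": "mc2_pyr",
      "excitation": "inhibitory"
    },
    {
      "id": "dbc_pyr1",
      "source": "mc1_rsnp",
      "target": "mc1_pyr",
      "excitation": "inhibitory"
    },
    {
      "id": "dbc_pyr2",
      "source": "mc2_rsnp",
      "target": "mc2_pyr",
      "excitation": "inhibitory"
    },
    {
      "id": "pyr1_basket",
      "source": "mc1_pyr",
      "target": "basket",
      "excitation": "excitatory"
    },
    {
      "id": "pyr1_dbc",
      "source": "mc1_pyr",
      "target": "mc2_rsnp",
      "excitation": "excitatory"
    },
    {
      "id": "pyr2_basket",
      "source": "mc2_pyr",
      "target": "basket",
      "excitation": "excitatory"
    },
    {
      "id": "pyr2_dbc",
      "source": "mc2_pyr",
      "target": "mc1_rsnp",
      "excitation": "excitatory"
    },
    {
      "id": "rec1",
      "source": "mc1_pyr",
      "target": "mc1_pyr",
      "excitation": "excitatory"
    },
    {
      "id": "rec2",
      "source": "mc2_pyr",
      "target": "mc2_pyr",
      "excitation": "excitatory"
    },
    {
      "id": "stim_pyr1",
      "source": "stim",
      "target": "mc1_pyr",
      "excitation": "excitatory"
    },
    {
      "id": "stim_pyr2",
      "source": "stim",
      "target": "mc2_pyr",
      "excitation": "excitatory"
    }
  ],
  "units": [
    {
      "id": "hc",
      "name": "Hypercolumn",
      "members": ["mc1", "mc2", "basket"]
    },
    {
      "id": "mc1",
      "name": "Minicolumn",
      "members": ["mc1_pyr", "mc1_rsnp"]
    },
    {
      "id": "mc2",
      "name": "Minicolumn",
      "members": ["mc2_pyr", "mc2_rsnp"]
    }
  ]
}
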