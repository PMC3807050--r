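{
  "format_version": "1.0",
  "metadata": {
    "title": "Synfire chain with feed-forward inhibition"
  },
  "populations": [
    {
      "id": "fs1",
      "label": {
        "ephys": "FS",
        "morph": "NPYR"
      }
    },
    {
      "id": "fs2",
      "label": {
        "ephys": "FS",
        "morph": "NPYR"
      }
    },
    {
      "id": "fs3",
      "label": {
        "ephys": "FS",
        "morph": "NPYR"
      }
    },
    {
      "id": "rs1",
      "label": {
        "ephys": "RS",
        "morph": "PYR"
      }
    },
    {
      "id": "rs2",
      "label": {
        "ephys": "RS",
        "morph": "PYR"
      }
    },
    {
      "id": "rs3",
      "label": {
        "ephys": "RS",
        "morph": "PYR"
      }
    },
    {
      "id": "stim",
      "label": {
        "ephys": "POIS"
      }
    }
  ],
  "projections": [
    {
      "id": "chain_fs1",
      "source": "rs1",
      "target": "fs2",
      "excitation": "excitatory"
    },
    {
      "id": "chain_fs2",
      "source": "rs2",
      "target": "fs3",
      "excitation": "excitatory"
    },
    {
      "id": "chain_rs1",
      "source": "rs1",
      "target": "rs2",
      "excitation": "excitatory"
    },
    {
      "id": "chain_rs2",
      "source": "rs2",
      "target": "rs3",
      "excitation": "excitatory"
    },
    {
      "id": "ffi1",
      "source": "fs1",
      "target": "rs1",
      "excitation": "inhibitory"
    },
    {
      "id": "ffi2",
      "source": "fs2",
      "target": "rs2",
      "excitation": "inhibitory"
    },
    {
      "id": "ffi3",
      "source": "fs3",
      "target": "rs3",
      "excitation": "inhibitory"
    },
    {
      "id": "stim_fs1",
      "source": "stim",
      "target": "fs1",
      "excitation": "excitatory"
    },
    {
      "id": "stim_rs1",
      "source": "stim",
      "target": "rs1",
      "excitation": "excitatory"
    }
  ],
  "units": [
    {
      "id": "group1",
      "name": "Group 1",
      "members": ["rs1", "fs1"]
    },
    {
      "id": "group2",
      "name": "Group 2",
      "members": ["rs2", "fs2"]
    },
    {
      "id": "group3",
      "name": "Group 3",
      "members": ["rs3", "fs3"]
    }
  ]
}
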