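{
  "format_version": "1.0",
  "metadata": {
    "title": "Thalamocortical regions"
  },
  "regions": [
    {
      "id": "area5",
      "kind": "area",
      "name": "Area 5",
      "display_order": 2
    },
    {
      "id": "thalamus",
      "kind": "ncr",
      "name": "Thalamus",
      "display_order": 1
    }
  ],
  "layers": [
    {
      "id": "area5.VI",
      "name": "VI",
      "area": "area5"
    }
  ],
  "populations": [
    {
      "id": "in",
      "label": {
        "ephys": "FS",
        "morph": "NPYR"
      },
      "layer": "area5.VI",
      "region": "area5"
    },
    {
      "id": "pyr",
      "label": {
        "ephys": "RS",
        "morph": "PYR"
      },
      "layer": "area5.VI",
      "region": "area5"
    },
    {
      "id": "re",
      "label": {
        "morph": "RE"
      },
      "region": "thalamus"
    },
    {
      "id": "tc",
      "label": {
        "morph": "TC"
      },
      "region": "thalamus"
    }
  ],
  "projections": [
    {
      "id": "in_pyr",
      "source": "in",
      "target": "pyr",
      "excitation": "inhibitory"
    },
    {
      "id": "pyr_pyr",
      "source": "pyr",
      "target": "pyr",
      "excitation": "excitatory"
    },
    {
      "id": "pyr_re",
      "source": "pyr",
      "target": "re",
      "excitation": "excitatory"
    },
    {
      "id": "pyr_tc",
      "source": "pyr",
      "target": "tc",
      "excitation": "excitatory"
    },
    {
      "id": "re_re",
      "source": "re",
      "target": "re",
      "excitation": "inhibitory"
    },
    {
      "id": "re_tc",
      "source": "re",
      "target": "tc",
      "excitation": "inhibitory"
    },
    {
      "id": "stim_pyr",
      "source": "EXTERNAL",
      "target": "pyr",
      "excitation": "excitatory"
    },
    {
      "id": "stim_tc",
      "source": "EXTERNAL",
      "target": "tc",
      "excitation": "excitatory"
    },
    {
      "id": "tc_in",
      "source": "tc",
      "target": "in",
      "excitation": "excitatory"
    },
    {
      "id": "tc_pyr",
      "source": "tc",
      "target": "pyr",
      "excitation": "excitatory"
    },
    {
      "id": "tc_re",
      "source": "tc",
      "target": "re",
      "excitation": "excitatory"
    }
  ]
}
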