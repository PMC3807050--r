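{
  "format_version": "1.0",
  "metadata": {
    "title": "Projection symbol examples"
  },
  "populations": [
    {
      "id": "pyr",
      "label": {
        "ephys": "RS",
        "morph": "PYR"
      }
    }
  ],
  "projections": [
    {
      "id": "in_exc",
      "source": "EXTERNAL",
      "target": "pyr",
      "excitation": "excitatory",
      "density": 0.5
    },
    {
      "id": "in_inh",
      "source": "EXTERNAL",
      "target": "pyr",
      "excitation": "inhibitory",
      "density": 0.1
    },
    {
      "id": "out_exc",
      "source": "pyr",
      "target": "EXTERNAL",
      "excitation": "excitatory",
      "density": 0.2
    },
    {
      "id": "self_exc",
      "source": "pyr",
      "target": "pyr",
      "excitation": "excitatory",
      "density": 0.2
    }
  ]
}
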