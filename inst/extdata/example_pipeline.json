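{
  "name": "example-run",
  "seed": 7,
  "stages": [
    {
      "type": "simulate",
      "preset": "olm",
      "protocols": [
        "complex_rec110"
      ],
      "out": "sim.csv"
    },
    {
      "type": "metrics",
      "data": "sim.csv",
      "protocol": "complex_rec110",
      "out": "metrics.json"
    }
  ]
}
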