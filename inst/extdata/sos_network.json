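{
  "nodes": ["ssDNA", "RecA", "LexA", "sigma70", "UmuDC", "SSB"],
  "input_node": "ssDNA",
  "edges": [
    {
      "from": "UmuDC",
      "sign": "-",
      "to": "ssDNA"
    },
    {
      "from": "SSB",
      "sign": "-",
      "to": "ssDNA"
    },
    {
      "from": "ssDNA",
      "sign": "+",
      "to": "RecA"
    },
    {
      "from": "UmuDC",
      "sign": "-",
      "to": "RecA"
    },
    {
      "from": "SSB",
      "sign": "-",
      "to": "RecA"
    },
    {
      "from": "RecA",
      "sign": "-",
      "to": "LexA"
    },
    {
      "from": "sigma70",
      "sign": "+",
      "to": "LexA"
    },
    {
      "from": "LexA",
      "sign": "-",
      "to": "sigma70"
    },
    {
      "from": "sigma70",
      "sign": "+",
      "to": "sigma70"
    },
    {
      "from": "LexA",
      "sign": "-",
      "to": "UmuDC"
    },
    {
      "from": "sigma70",
      "sign": "+",
      "to": "UmuDC"
    },
    {
      "from": "LexA",
      "sign": "-",
      "to": "SSB"
    },
    {
      "from": "sigma70",
      "sign": "+",
      "to": "SSB"
    }
  ]
}
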