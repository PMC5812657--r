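{
  "rules": [
    {
      "scope_type": "species",
      "scope": "Bokermannohyla_alvarengai",
      "raw": "4",
      "state": "4a"
    },
    {
      "scope_type": "species",
      "scope": "Hyloscirtus_alytolylax",
      "raw": "4",
      "state": "4b"
    },
    {
      "scope_type": "species",
      "scope": "Hyloscirtus_palmeri",
      "raw": "4",
      "state": "4c"
    },
    {
      "scope_type": "*",
      "scope": "*",
      "raw": "9",
      "state": "11"
    },
    {
      "scope_type": "genus",
      "scope": "Aplastodiscus",
      "raw": "6",
      "state": "6"
    },
    {
      "scope_type": "genus",
      "scope": "Aplastodiscus",
      "raw": "7",
      "state": "6"
    },
    {
      "scope_type": "genus",
      "scope": "Aplastodiscus",
      "raw": "6or7",
      "state": "6"
    },
    {
      "scope_type": "genus",
      "scope": "Boana",
      "raw": "7",
      "state": "7"
    },
    {
      "scope_type": "*",
      "scope": "*",
      "raw": "1",
      "state": "1"
    },
    {
      "scope_type": "*",
      "scope": "*",
      "raw": "2",
      "state": "2"
    },
    {
      "scope_type": "*",
      "scope": "*",
      "raw": "6",
      "state": "6"
    },
    {
      "scope_type": "*",
      "scope": "*",
      "raw": "8",
      "state": "8"
    },
    {
      "scope_type": "*",
      "scope": "*",
      "raw": "11",
      "state": "11"
    },
    {
      "scope_type": "*",
      "scope": "*",
      "raw": "12",
      "state": "12"
    }
  ],
  "alphabet": ["1", "2", "4a", "4b", "4c", "6", "7", "8", "11", "12"],
  "medium_rule": "genus"
}
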