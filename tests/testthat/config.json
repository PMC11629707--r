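{
  "command": "fit",
  "options": {
    "input": "no-such-file.csv"
  },
  "package_version": "0.1.0",
  "seed": null,
  "n_starts": 50,
  "config_hash": "b7864c2f1fdd15b9e328f36424e42657"
}
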