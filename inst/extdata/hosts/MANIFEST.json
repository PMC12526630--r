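{
  "provenance": "synthetic",
  "description": "Codon usage tables generated by a compositional model emulating each species' third-position GC preference; not database snapshots.",
  "generator": "scratch/make_hosts.R (deterministic, no RNG)",
  "species": {
    "Escherichia_coli": {
      "target_gc3s": 0.55
    },
    "Saccharomyces_cerevisiae": {
      "target_gc3s": 0.38
    },
    "Arabidopsis_thaliana": {
      "target_gc3s": 0.42
    },
    "Nicotiana_tabacum": {
      "target_gc3s": 0.41
    },
    "Triticum_aestivum": {
      "target_gc3s": 0.62
    },
    "Zea_mays": {
      "target_gc3s": 0.63
    }
  }
}
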