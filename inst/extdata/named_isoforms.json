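[
  {
    "label": "p53ψ",
    "gene": "TP53",
    "event_type": "cryptic_acceptor",
    "intron": 6,
    "distance": -49,
    "note": "Truncated TP53 isoform produced via a cryptic splice acceptor 49 bp upstream of the canonical intron 6 acceptor; carries a premature termination codon."
  }
]
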