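[
  {
    "motif_id": "kB_core",
    "tf": "NFkB",
    "kind": "iupac",
    "pattern": "GGGRNNY",
    "note": "Minimal kB half-site core recognised by NFkB dimers."
  },
  {
    "motif_id": "kB_consensus",
    "tf": "NFkB",
    "kind": "iupac",
    "pattern": "GGGRNNYYCC",
    "note": "Canonical 10-bp kB consensus family."
  },
  {
    "motif_id": "Sp1_GC_box",
    "tf": "Sp1",
    "kind": "iupac",
    "pattern": "KRGGCKRRK",
    "note": "Sp1 GC-box consensus."
  },
  {
    "motif_id": "Sp1_GT_box",
    "tf": "Sp1",
    "kind": "iupac",
    "pattern": "GGTGTSSY",
    "note": "Sp1 GT-box variant; terminal pyrimidine tolerated at degenerate position."
  }
]
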