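[
  {
    "name": "karate",
    "file": "karate.gml",
    "nodes": 34,
    "edges": 78,
    "source": "Zachary (1977) karate club friendship network, topology only, members 1-34",
    "md5": "e46f6e8483fd96493311a5331977489d"
  },
  {
    "name": "florentine",
    "file": "florentine.gml",
    "nodes": 15,
    "edges": 20,
    "source": "Padgett Florentine marriage ties, 15-family connected component (isolated Pucci omitted)",
    "md5": "d942f4be0fb3e9bc37c37571acdd67fd"
  },
  {
    "name": "lesmis",
    "file": "lesmis.gml",
    "nodes": 77,
    "edges": 254,
    "source": "Knuth (1993) Les Miserables chapter coappearance network, topology only",
    "md5": "d8c05edd1551bcfe4ffa92f30071e64f"
  }
]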