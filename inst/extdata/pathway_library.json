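{
  "library_name": "synthetic-bee-hemolymph-pathways",
  "version": "1.0",
  "synthetic": true,
  "comment": "Small synthetic pathway library for testing and demonstration. Memberships are trimmed/adjusted toy versions of the named pathways, not a curated database.",
  "pathways": [
    {
      "name": "Starch and sucrose metabolism",
      "members": ["sucrose", "fructose", "trehalose", "glucose", "maltose",
                  "glucose 1-phosphate", "udp-glucose"],
      "edges": [["maltose", "glucose"], ["glucose", "sucrose"],
                ["sucrose", "fructose"], ["glucose", "glucose 1-phosphate"],
                ["glucose 1-phosphate", "udp-glucose"],
                ["udp-glucose", "trehalose"], ["trehalose", "glucose"]]
    },
    {
      "name": "Aminoacyl-tRNA biosynthesis",
      "members": ["aminoacyl-trna", "histidine", "arginine", "asparagine",
                  "glutamine", "aspartic acid", "glutamic acid", "proline",
                  "tryptophan"],
      "edges": [["aminoacyl-trna", "histidine"], ["aminoacyl-trna", "arginine"],
                ["aminoacyl-trna", "asparagine"], ["aminoacyl-trna", "glutamine"],
                ["aminoacyl-trna", "aspartic acid"],
                ["aminoacyl-trna", "glutamic acid"],
                ["aminoacyl-trna", "proline"], ["aminoacyl-trna", "tryptophan"]]
    },
    {
      "name": "Alanine, aspartate and glutamate metabolism",
      "members": ["asparagine", "glutamine", "aspartic acid", "alanine",
                  "oxaloacetate", "fumarate"],
      "edges": [["glutamine", "asparagine"], ["asparagine", "aspartic acid"],
                ["aspartic acid", "oxaloacetate"],
                ["aspartic acid", "fumarate"], ["aspartic acid", "alanine"]]
    },
    {
      "name": "Arginine and proline metabolism",
      "members": ["arginine", "proline", "homoserine", "ornithine",
                  "citrulline", "putrescine", "glutamate-5-semialdehyde"],
      "edges": [["arginine", "ornithine"], ["ornithine", "citrulline"],
                ["citrulline", "arginine"], ["ornithine", "putrescine"],
                ["ornithine", "glutamate-5-semialdehyde"],
                ["glutamate-5-semialdehyde", "proline"],
                ["homoserine", "glutamate-5-semialdehyde"]]
    },
    {
      "name": "D-Glutamine and D-glutamate metabolism",
      "members": ["glutamine", "glutamic acid", "asparagine", "d-glutamate",
                  "5-oxoproline"],
      "edges": [["glutamine", "glutamic acid"],
                ["glutamic acid", "d-glutamate"], ["glutamine", "asparagine"],
                ["glutamic acid", "5-oxoproline"]]
    },
    {
      "name": "Purine metabolism",
      "members": ["hypoxanthine", "inosine", "xanthine", "urate", "adenine"],
      "edges": [["adenine", "inosine"], ["inosine", "hypoxanthine"],
                ["hypoxanthine", "xanthine"], ["xanthine", "urate"]]
    },
    {
      "name": "Phenylalanine metabolism",
      "members": ["phenylacetic acid", "phenylacetaldehyde", "styrene",
                  "phenylalanine", "trans-cinnamic acid"],
      "edges": [["phenylalanine", "phenylacetaldehyde"],
                ["phenylacetaldehyde", "phenylacetic acid"],
                ["phenylalanine", "trans-cinnamic acid"],
                ["phenylalanine", "styrene"]]
    },
    {
      "name": "Benzoate degradation",
      "members": ["4-hydroxybenzoic acid", "3-hydroxybenzoic acid",
                  "vanillic acid", "3,4-dihydroxybenzoic acid", "benzoic acid"],
      "edges": [["benzoic acid", "4-hydroxybenzoic acid"],
                ["benzoic acid", "3-hydroxybenzoic acid"],
                ["4-hydroxybenzoic acid", "3,4-dihydroxybenzoic acid"],
                ["3,4-dihydroxybenzoic acid", "vanillic acid"]]
    }
  ]
}
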