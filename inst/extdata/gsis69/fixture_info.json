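{
  "name": "gsis69",
  "description": "69 protein components of the core glucose-stimulated insulin secretion (GSIS) biochemical network of the pancreatic beta-cell, with human-mouse percent similarity, sub-pathway codes, phylogenetic age class, positive-selection episodes and OMIM disease associations.",
  "n_records": 69,
  "genome_reference_proportions": {"U": 0.56, "E": 0.20, "M": 0.05, "V": 0.19},
  "pathway_codes": {
    "G": "glycolysis", "T": "TCA cycle", "P": "pyruvate cycle",
    "N": "NADH shuttle", "R": "respiratory chain",
    "M": "metabolite transport", "S": "glutathione pathway"
  },
  "excluded_transporters": [
    {"id": "Q4A5HQ1", "name": "pyruvate carrier"},
    {"id": "O43837", "name": "isocitrate dehydrogenase NAD+ beta"},
    {"id": "Q00325", "name": "phosphate carrier"},
    {"id": "Q59GB0", "name": "aspartate/glutamate carrier"},
    {"id": "P12236", "name": "ATP/ADP carrier"}
  ],
  "notes": "Five mouse transporters without identifiable human orthologue pairs are excluded, fixing n = 69. The selection table transcribes the printed per-lineage episodes (16 rows); the source text's episode total (17, with five rather than four episodes for Cox4a) cannot be reconciled with the printed table, so the table is taken as authoritative. Disease table gene symbols are normalised to the protein table abbreviations (GCK -> GK, SOD2 m -> SOD2m, Cox8A -> Cox8a, Cox7R -> Cox7r, Cox4A -> Cox4a)."
}
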