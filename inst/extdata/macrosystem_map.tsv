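subsystem	macrosystem
Alanine and Aspartate Metabolism	Amino acid metabolism
Arginine and Proline Metabolism	Amino acid metabolism
Cysteine Metabolism	Amino acid metabolism
Glutamate Metabolism	Amino acid metabolism
Glycine and Serine Metabolism	Amino acid metabolism
Histidine Metabolism	Amino acid metabolism
Methionine Metabolism	Amino acid metabolism
Threonine and Lysine Metabolism	Amino acid metabolism
Tyrosine, Tryptophan, and Phenylalanine Metabolism	Amino acid metabolism
Valine, Leucine, and Isoleucine Metabolism	Amino acid metabolism
Citric Acid Cycle	Carbohydrate metabolism
Glycolysis/Gluconeogenesis	Carbohydrate metabolism
Glyoxylate Metabolism	Carbohydrate metabolism
Pentose Phosphate Pathway	Carbohydrate metabolism
Pyruvate Metabolism	Carbohydrate metabolism
Alternate Carbon Metabolism	Carbohydrate metabolism
Anaplerotic Reactions	Carbohydrate metabolism
Methylglyoxal Metabolism	Carbohydrate metabolism
Oxidative Phosphorylation	Energy and maintenance
Unassigned	Energy and maintenance
Cell Envelope Biosynthesis	Cell wall biosynthesis
Murein Biosynthesis	Cell wall biosynthesis
Murein Recycling	Cell wall biosynthesis
Lipopolysaccharide Biosynthesis / Recycling	Cell wall biosynthesis
Cofactor and Prosthetic Group Biosynthesis	Cofactor and vitamin metabolism
Folate Metabolism	Cofactor and vitamin metabolism
Glycerophospholipid Metabolism	Lipid metabolism
Membrane Lipid Metabolism	Lipid metabolism
Lipid Metabolism	Lipid metabolism
Nucleotide Salvage Pathway	Nucleotide metabolism
Purine and Pyrimidine Biosynthesis	Nucleotide metabolism
tRNA Charging	Nucleotide metabolism
Transport, Inner Membrane	Transport
Transport, Outer Membrane	Transport
Transport, Outer Membrane Porin	Transport
Inorganic Ion Transport and Metabolism	Transport
Extracellular exchange	Transport
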