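percent_of_cell_type	percent_of_query_gene_list	cell_type
0.6	0.75	smooth muscle cells - uterine
0.1538	0.25	smooth muscle cells - pulmonary artery
0.0769	0.125	heart fetal
0.0667	0.125	mesenchymal stem cells - amniotic membrane
0.0556	0.125	myoblast
0.0323	0.125	renal proximal tubular epithelial cell
0.0244	0.125	fibroblast - lymphatic
0.0185	0.125	heart - mitral valve adult
0.0169	0.125	chondrocyte - de diff
0.0169	0.125	thyroid fetal
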