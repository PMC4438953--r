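side	node	degree
miRNA	hsa-miR-494	22
miRNA	hsa-miR-183	14
miRNA	hsa-miR-96	11
miRNA	hsa-miR-374a	10
miRNA	hsa-miR-21	6
miRNA	hsa-miR-455-3p	6
miRNA	hsa-miR-542-3p	6
miRNA	hsa-miR-490-5p	5
miRNA	hsa-miR-15b	4
miRNA	hsa-miR-7	4
miRNA	hsa-let-7f	3
miRNA	hsa-miR-98	3
miRNA	hsa-miR-192	2
miRNA	hsa-miR-34b	2
miRNA	hsa-miR-375	2
go_term	Regulation of transcription, DNA-dependent	12
go_term	Transcription	9
go_term	Development	8
go_term	Signal transduction	6
go_term	Apoptosis	5
go_term	Cell differentiation	5
go_term	Cell cycle	4
go_term	Cell cycle arrest	4
go_term	Cell division	4
go_term	Negative regulation of progression through cell cycle	3
go_term	Positive regulation of transcription from RNA polymerase II promoter	3
go_term	Rhythmic process	3
go_term	Cell aging	2
go_term	Cytokinesis	2
go_term	Negative regulation of JNK activity	2
go_term	Negative regulation of transcription from RNA polymerase II promoter	2
go_term	Organic anion transport	2
go_term	Protein amino acid phosphorylation	2
go_term	Response to hypoxia	2
go_term	Transcription from RNA polymerase II promoter	2
go_term	Actin modification	1
go_term	Cell dedifferentiation	1
go_term	Cellular response to insulin stimulus	1
go_term	Chromatin remodeling	1
go_term	G1 phase of mitotic cell cycle	1
go_term	Glucose homeostasis	1
go_term	Insulin-like growth factor receptor signaling pathway	1
go_term	Leukemia inhibitory factor signaling pathway	1
go_term	NAD metabolism	1
go_term	Negative regulation of epithelial cell proliferation	1
go_term	Negative regulation of insulin-like growth factor receptor signaling pathway	1
go_term	Phosphoinositide 3-kinase cascade	1
go_term	Positive regulation of fibroblast proliferation	1
go_term	Positive regulation of glucose import	1
go_term	Positive regulation of mitotic metaphase/anaphase transition	1
go_term	Protein kinase B signaling cascade	1
go_term	Response to cytokine stimulus	1
go_term	Response to peptide hormone stimulus	1
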