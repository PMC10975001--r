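feature_id	category	type_th_vs_thc	type_p_vs_pc
2,3,19-Trihydroxyurs-12-en-28-oic acid	Terpenoids	up	up
Pinfaensic acid	Terpenoids	up	up
N,N'-Dimethylarginine; SDMA	Amino acids and derivatives	up	up
N-Monomethyl-L-arginine	Amino acids and derivatives	up	up
L-Isoleucyl-L-Aspartate	Amino acids and derivatives	up	up
L-Aspartyl-L-Phenylalanine	Amino acids and derivatives	up	up
Candelabrone 12-methyl ether	Terpenoids	up	up
19-Hydroxyursolic acid	Terpenoids	up	up
Homoarginine	Amino acids and derivatives	up	up
NG,NG-Dimethyl-L-arginine	Amino acids and derivatives	up	up
2-Deoxyribose-1-phosphate	Nucleotides and derivatives	up	up
6'-O-Feruloyl-D-sucrose	Phenolic acids	up	up
Jasmonic acid	Organic acids	up	up
2-Acetoxymethyl-anthraquinone	Quinones	up	up
Propyl 4-hydroxybenzoate	Phenolic acids	up	up
5-hydroxy-1-phenyl-7-3-heptanone	Others	up	up
2,2-Dimethylsuccinic acid	Organic acids	up	up
L-Tartaric acid	Organic acids	up	down
Tachioside	Phenolic acids	down	down
Isotachioside	Phenolic acids	down	down
1-O-Salicyloyl-beta-D-glucose	Phenolic acids	down	down
Salicylic acid-2-O-glucoside	Phenolic acids	down	down
p-Hydroxypheny-beta-D-allopyranoside	Phenolic acids	down	down
Arbutin	Phenolic acids	down	down
Sinapoyl malate	Phenolic acids	down	down
2-O-Caffeoylglucaric Acid	Phenolic acids	down	down
Oleic acid	Lipids	down	down
N-Methyl-Trans-4-Hydroxy-L-Proline	Amino acids and derivatives	down	down
2,6-Dimethoxy-4-hydroxyphenol-1-O-beta-D-glucopyranoside	Others	down	down
Methoxyindoleacetic acid	Alkaloids	down	up
Tryptamine	Alkaloids	down	up
L-Tryptophan	Amino acids and derivatives	down	up
3-Indoleacetonitrile	Alkaloids	down	up
1-Methoxy-indole-3-acetamide	Alkaloids	down	up
Indole	Alkaloids	down	up
3-Indolepropionic acid	Alkaloids	down	up
3-Indoleacrylic acid	Alkaloids	down	up
gamma-glutamylmethionine	Amino acids and derivatives	down	up
2-Aminoethanesulfonic acid	Organic acids	down	up
p-Coumaric acid methyl ester	Phenolic acids	down	up
Roseoside	Others	down	up
Isoquinoline	Alkaloids	down	up
4-caffeoylshikimic acid	Phenolic acids	down	up
L-Histidine	Amino acids and derivatives	down	up
Phlorizin	Flavonoids	down	up
3,4-Methylenedioxy cinnamyl alcohol	Lignans and Coumarins	down	up
Kaurenoic Acid	Terpenoids	down	up
LysoPC 15:0	Lipids	down	up
Melibiose	Others	down	up
3-amino-2-naphthoic acid	Alkaloids	down	up
L-Lysine-Butanoic Acid	Amino acids and derivatives	down	up
cyclo-(Gly-Phe)	Amino acids and derivatives	down	up
Trans-Citridic acid	Organic acids	down	up
1-O-Sinapoyl-beta-D-glucose	Phenolic acids	down	up
Linarin	Flavonoids	down	up
Syringaresinol-4'-O-glucoside	Lignans and Coumarins	down	up
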