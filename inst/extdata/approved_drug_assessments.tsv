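# Published screening measurements for the ten approved NSCLC drugs that
# pass the association test: rating scores (mean combined interaction
# score) and permutation-test P-values against NSCLC-related chemicals
# and genes. Used to derive the drug-based P-value thresholds.
compound	name	rs_chemicals	rs_genes	pvalue_chemicals	pvalue_genes
4033	Mechlorethamine	296.299	358.250	0.248	0.115
36314	Paclitaxel	306.485	462.889	0.346	0.221
38904	Carboplatin	307.897	332.267	0.196	0.238
57166	Porfimer Sodium	307.231	218.000	0.312	0.032
60843	Pemetrexed	278.798	233.750	0.337	0.124
123631	Gefitinib	303.047	493.275	0.289	0.292
126941	Methotrexate	330.201	362.250	0.469	0.150
176870	Erlotinib	320.090	579.929	0.273	0.175
10184653	Afatinib	365.038	451.091	0.128	0.063
11626560	Crizotinib	293.407	579.500	0.263	0.187
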