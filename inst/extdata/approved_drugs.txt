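# Sixteen approved NSCLC drugs (PubChem CIDs)
CID4033	# Mechlorethamine
CID36314	# Paclitaxel
CID38904	# Carboplatin
CID57166	# Porfimer Sodium
CID60750	# Gemcitabine
CID60780	# Vinorelbine
CID60843	# Pemetrexed
CID123631	# Gefitinib
CID126941	# Methotrexate
CID148124	# Docetaxel
CID176870	# Erlotinib
CID441203	# Cisplatin
CID5360373	# Bleomycin
CID10184653	# Afatinib
CID11626560	# Crizotinib
CID57379345	# Ceritinib
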