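phylum,live_n,dead_n,live_s,dead_s
Mollusca,3076,53151,87,128
Arthropoda,2944,60,49,15
Annelida,1640,574,6,3
Echinodermata,1092,249,11,7
Cnidaria,39,82,3,2
Brachiopoda,7,0,1,0
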