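class,live_n,dead_n,live_s,dead_s
Malacostracea,2944,57,49,14
Gastropoda,2103,5465,42,49
Polychaeta,1640,574,6,3
Bivalvia,890,47660,44,78
Echinoidea,877,249,5,7
Ophioroidea,82,0,2,0
Asteroidea,133,0,4,0
Anthozoa,39,82,3,2
Lingulida,7,0,1,0
Scaphopoda,83,26,1,1
Merostomata,0,3,0,1
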