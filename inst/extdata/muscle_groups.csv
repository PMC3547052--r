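muscle,abbreviation,functional_group,n_beams
M. Adductor Mandibulae Externus Superficialis,MAMES,temporal,40
M. Adductor Mandibulae Externus Medius,MAMEM,temporal,26
M. Adductor Mandibulae Externus Profundus,MAMEP,temporal,18
M. Adductor Mandibulae Posterior,MAMP,temporal,46
Pseudotemporalis,PST,temporal,8
Pterygoidus Anterior,PTA,pterygoid,84
Pterygoidus Posterior,PTP,pterygoid,76
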