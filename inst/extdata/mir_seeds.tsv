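family	seed
let-7-5p	GAGGUAG
miR-1-3p	GGAAUGU
miR-7-5p	GGAAGAC
miR-9-5p	CUUUGGU
miR-21-5p	AGCUUAU
miR-22-3p	AGCUGCC
miR-26-5p	UCAAGUA
miR-29-3p	AGCACCA
miR-30-5p	GUAAACA
miR-34-5p	GGCAGUG
miR-103-3p	GCAGCAU
miR-124-3p	AAGGCAC
miR-128-3p	CACAGUG
miR-133-3p	UUGGUCC
miR-137-3p	UAUUGCU
miR-138-5p	GCUGGUG
miR-153-3p	UGCAUAG
miR-181-5p	ACAUUCA
miR-218-5p	UGUGCUU
miR-219-5p	GAUUGUC
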