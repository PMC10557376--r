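# Common contaminant protein accessions (human keratins, trypsin and other
# frequent laboratory contaminants). One UniProt accession per line.
P04264  # KRT1_HUMAN keratin, type II cytoskeletal 1
P35908  # K22E_HUMAN keratin, type II cytoskeletal 2 epidermal
P13645  # K1C10_HUMAN keratin, type I cytoskeletal 10
P35527  # K1C9_HUMAN keratin, type I cytoskeletal 9
P02533  # K1C14_HUMAN keratin, type I cytoskeletal 14
P08779  # K1C16_HUMAN keratin, type I cytoskeletal 16
P04259  # K2C6B_HUMAN keratin, type II cytoskeletal 6B
P48668  # K2C6C_HUMAN keratin, type II cytoskeletal 6C
P19013  # K2C4_HUMAN keratin, type II cytoskeletal 4
P08729  # K2C7_HUMAN keratin, type II cytoskeletal 7
P05787  # K2C8_HUMAN keratin, type II cytoskeletal 8
P13646  # K1C13_HUMAN keratin, type I cytoskeletal 13
P02538  # K2C6A_HUMAN keratin, type II cytoskeletal 6A
P00761  # TRYP_PIG trypsin (porcine)
P00760  # TRY1_BOVIN cationic trypsin (bovine)
P02769  # ALBU_BOVIN bovine serum albumin
P00883  # ALDOA_RABIT aldolase (rabbit)
Q32MB2  # keratin-associated
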