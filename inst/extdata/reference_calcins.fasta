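>IpTxA_P59868 Imperatoxin-A mature peptide, Pandinus imperator (transcribed from UniProt P59868)
GDCLPHLKRCKADNDCCGKKCKRRGTNAEKRCR
>maurocalcin_P60254 Maurocalcin mature peptide, Scorpio maurus palmatus (transcribed from UniProt P60254)
GDCLPHLKLCKENKDCCSKKCKRRGTNIEKRCR
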