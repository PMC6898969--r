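gene	panel
RIPK1	death
RIPK3	death
MLKL	death
RNF11	death
CYLD	death
LOX	death
HSP70	death
TNFAIP3	death
CASP3	death
CASP7	death
TNFR1	death
TNFR2	survival
CASP8	survival
TRADD	survival
FADD	survival
CFLAR	survival
IKK-B	survival
NFKB	survival
RELA	survival
AKT	survival
XIAP	survival
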