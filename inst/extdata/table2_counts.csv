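# Fracture x observer-score cell counts for the 304-subject cohort.
# The six cells are the unique completion of the published margins:
# row totals 115 (fractured) / 189 (fracture-free), column totals
# 49 / 146 / 109 (dense / alternating / sparse), grand total 304,
# with the fracture-free row printed as 48 / 111 / 30; the fractured row
# follows by subtraction: 49-48=1, 146-111=35, 109-30=79.
outcome,dense,alternating,sparse
fractured,1,35,79
fracture_free,48,111,30
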