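chrom	start	end	name	methylated_allele
chr1	39559298	39559744	PPIEL:Ex1-DMR	maternal
chr1	68512500	68513400	DIRAS3:Ex2-DMR	maternal
chr4	89618200	89619000	NAP1L5:TSS-DMR	maternal
chr5	135416100	135416800	VTRNA2-1:DMR	maternal
chr6	3849096	3849469	FAM50B:TSS-DMR	maternal
chr6	144328700	144329700	PLAGL1:alt-TSS-DMR	maternal
chr7	94285600	94286600	PEG10:TSS-DMR	maternal
chr11	2019300	2021300	H19/IGF2:IG-DMR	paternal
chr11	2720400	2721400	KCNQ1OT1:TSS-DMR	maternal
chr14	101292000	101293000	MEG3:TSS-DMR	paternal
chr15	99408600	99409400	IGF1R:Int2-DMR	maternal
chr21	40757600	40758400	WRB:alt-TSS-DMR	maternal
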