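gene	chrom	start_bp	end_bp	note
B3GALNT2	1	42000000	42120000	congenital hydrocephalus (autosomal recessive); synthetic placeholder coordinates
PLOD1	2	18500000	18540000	warmblood fragile foal syndrome (autosomal recessive); synthetic placeholder coordinates
MUTYH	2	31200000	31230000	cerebellar abiotrophy (autosomal recessive); synthetic placeholder coordinates
STX17	25	28000000	28060000	grey coat colour (autosomal dominant); synthetic placeholder coordinates
GBE1	26	24000000	24250000	glycogen branching enzyme deficiency (autosomal recessive); synthetic placeholder coordinates
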