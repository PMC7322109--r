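# Printed per-period totals and grand total of the same motif distribution
# table. The printed trinucleotide subtotal (1806) differs from the sum of
# its printed class rows (1860); the table's own percentage columns are
# consistent with these printed subtotals, so they are kept verbatim here.
type	total
mono	19706
di	5154
tri	1806
tetra	309
penta	60
hexa	64
all	27153
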