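# Avian control-region conserved-element consensus library.
# Condensed IUPAC core consensi assembled from the avian D-loop
# literature (goose/chicken/raptor alignments); editable configuration,
# not code. max_mismatch is the per-motif Hamming allowance used by the
# scanner. ETAS2/CSB2/CSB3 are included so their absence can be reported.
name	pattern	max_mismatch
ETAS1	TACATAWTATGTATWATCGTGCAT	3
ETAS2	TACATAGTACATTAWATGTATGAT	2
FBOX	ATGGCCCTGACYTAGGAACCAGRT	2
EBOX	AGGGACYCATTCAGGAGAWGGTYA	2
DBOX	CCTGGTTGGTYGGAGCAGGATTTA	2
CBOX	TAAACCCATRTCACGWGAAATCAG	2
CSBA	TTCGTGCAYGCWTAGGCAACCATT	2
CSBB	GTTCAAGGCCTATKGGTTCCYGGG	2
BIRDBOX	CAAYGATAGCTTGYTTCAGGCACA	3
CSB1	TTGGTTGAATGRGCWTACGACATA	2
CSB2	CAAACCCCCCCTACCCCCCTAAAC	2
CSB3	TGCCAAACCCCAAAAACGAGACTA	2
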