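# Default single-copy marker set for reduced CPR-like genomes: a 43-marker
# ribosomal-protein-centric reconstruction (editable; supply your own set for
# other lineages). One identifier per line; matching is case-insensitive.
rpL2
rpL3
rpL4
rpL5
rpL6
rpL14
rpL15
rpL16
rpL18
rpL22
rpL24
rpS3
rpS8
rpS10
rpS17
rpS19
rpL1
rpL13
rpL17
rpL19
rpL20
rpL21
rpL27
rpL28
rpL29
rpS2
rpS4
rpS5
rpS6
rpS7
rpS9
rpS11
rpS12
rpS13
rpS15
rpS16
rpS18
rpS20
infC
secY
ffh
rpoB
gyrA
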