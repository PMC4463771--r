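lipid_class	polarity	kind	adduct
TAG	+	neutral-loss-of-FA	+NH4
PC	+	headgroup	+H
PC	+	precursor	+H
SM	+	headgroup	+H
SM	+	precursor	+H
PC	-	fa-anion	+HCOO
PE	-	fa-anion	-H
PI	-	fa-anion	-H
PS	-	fa-anion	-H
PS	-	serine-loss	-H
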