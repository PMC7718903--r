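# Reduced residue-level contact potential for poly-alanine heavy atoms.
# Distance bins (A): [0,2.5) clash (strongly repulsive so burial never pays), [2.5,3.5) close contact, [3.5,5) contact,
# [5,7) near, [7,10) distal. Higher value = more favourable.
# Membrane-bead rows are filled automatically with membrane_penalty.
# SG (thiol-like hot-spot) pairs are strongly favourable: complementary
# hot-spot patches dominate the binding-site registration, as interface
# hot spots do in real complexes.
types N CA C O CB SG
bins 0 2.5 3.5 5.0 7.0 10.0
membrane_penalty -999.0
pair N  N   -100.0  0.50  2.00  1.00  0.25
pair N  CA  -100.0  0.50  2.00  1.00  0.25
pair N  C   -100.0  0.50  2.00  1.00  0.25
pair N  O   -100.0  1.50  2.50  1.00  0.25
pair N  CB  -100.0  0.50  2.00  1.00  0.25
pair CA CA  -100.0  0.50  2.00  1.00  0.25
pair CA C   -100.0  0.50  2.00  1.00  0.25
pair CA O   -100.0  0.50  2.00  1.00  0.25
pair CA CB  -100.0  0.75  2.25  1.00  0.25
pair C  C   -100.0  0.50  2.00  1.00  0.25
pair C  O   -100.0  0.50  2.00  1.00  0.25
pair C  CB  -100.0  0.50  2.00  1.00  0.25
pair O  O   -100.0  0.50  2.00  1.00  0.25
pair O  CB  -100.0  0.50  2.00  1.00  0.25
pair CB CB  -100.0  1.00  3.00  1.50  0.25
pair SG N   -100.0  0.50  2.00  1.00  0.25
pair SG CA  -100.0  0.50  2.00  1.00  0.25
pair SG C   -100.0  0.50  2.00  1.00  0.25
pair SG O   -100.0  0.50  2.00  1.00  0.25
pair SG CB  -100.0  0.75  2.25  1.00  0.25
pair SG SG  -100.0 120.00 150.00 60.00 15.00
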