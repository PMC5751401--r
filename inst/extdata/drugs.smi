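CC(=O)Oc1ccccc1C(=O)O	aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C	caffeine
CC(C)Cc1ccc(cc1)C(C)C(=O)O	ibuprofen
CC(=O)Nc1ccc(O)cc1	paracetamol
COc1ccc2cc(ccc2c1)C(C)C(=O)O	naproxen
CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1	diazepam
CN1CCCC1c1cccnc1	nicotine
Clc1ccccc1-c1ccc2nc(N)nc(N)c2n1	synthetic_diamine
OCCN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc32)CC1	perphenazine_core
NC(=O)c1ccc[nH]1	pyrrole_amide
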