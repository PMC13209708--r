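id,smiles
BMDM,CC(C)(C)c1ccc(cc1)C(=O)CC(=O)c1ccc(OC)cc1
BP-3,COc1ccc(C(=O)c2ccccc2)c(O)c1
DHHB,CCCCCCOC(=O)c1ccccc1C(=O)c1ccc(cc1O)N(CC)CC
PABA,Nc1ccc(cc1)C(=O)O
EHDP,CCCCC(CC)COC(=O)c1ccc(cc1)N(C)C
Et-PABA,CCOC(=O)c1ccc(N)cc1
PBSA,OS(=O)(=O)c1ccc2[nH]c(-c3ccccc3)nc2c1
MBC,CC1(C)C2CCC1(C)C(=O)C2=Cc1ccc(C)cc1
EHMC,CCCCC(CC)COC(=O)C=Cc1ccc(OC)cc1
IMC,CC(C)CCOC(=O)C=Cc1ccc(OC)cc1
OCR,CCCCC(CC)COC(=O)C(=C(c1ccccc1)c1ccccc1)C#N
ET,CCCCC(CC)COC(=O)c1ccc(Nc2nc(Nc3ccc(cc3)C(=O)OCC(CC)CCCC)nc(Nc3ccc(cc3)C(=O)OCC(CC)CCCC)n2)cc1
OS,CCCCC(CC)COC(=O)c1ccccc1O
HMS,CC1CC(C)(C)CC(C1)OC(=O)c1ccccc1O
DOBT,CC(C)(C)NC(=O)c1ccc(Nc2nc(Nc3ccc(cc3)C(=O)OCC(CC)CCCC)nc(Nc3ccc(cc3)C(=O)OCC(CC)CCCC)n2)cc1
BZ-4,COc1cc(c(cc1O)C(=O)c1ccccc1)S(=O)(=O)O
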