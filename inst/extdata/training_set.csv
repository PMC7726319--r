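id,smiles,label
glycyrrhizin,CC1(C2CCC3(C(C2(CCC1OC4C(C(C(C(O4)C(=O)O)O)O)OC5C(C(C(C(O5)C(=O)O)O)O)O)C)C(=O)C=C6C3(CCC7(C6CC(CC7)(C)C(=O)O)C)C)C)C,active
carbenoxolone,CC1(CCC2(CCC3(C(C2C1)C(=O)C=C4C3(CCC5C4(CCC(C5(C)C)OC(=O)CCC(=O)O)C)C)C)C(=O)O)C,active
salicylic_acid,OC(=O)c1ccccc1O,active
amorfrutin_A,CC(C)=CCc1c(O)c(C(O)=O)c(CCc2ccccc2)cc1OC,active
ac3aesa,CC(=O)NCCc1cccc(C(O)=O)c1O,active
diflunisal,OC(=O)c1cc(-c2ccc(F)cc2F)ccc1O,active
inflachromene_synthetic,CC1(C)C=Cc2c(O1)cc(OC)c(CC(=O)N(C)C)c2O,active
acetaminophen,CC(=O)Nc1ccc(O)cc1,decoy
ibuprofen,CC(C)Cc1ccc(C(C)C(=O)O)cc1,decoy
naproxen,COc1ccc2cc(C(C)C(=O)O)ccc2c1,decoy
nimesulide,CS(=O)(=O)Nc1ccc([N+](=O)[O-])cc1Oc1ccccc1,decoy
ketoprofen,CC(C(=O)O)c1cccc(C(=O)c2ccccc2)c1,decoy
folic_acid,Nc1nc2ncc(CNc3ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc3)nc2c(=O)[nH]1,decoy
tetrahydromethotrexate,CN(CC1CNc2nc(N)nc(N)c2N1)c1ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc1,decoy
cortisol,CC12CCC(=O)C=C1CCC3C2C(O)CC4(C)C3CCC4(O)C(=O)CO,decoy
cortisone,CC12CCC(=O)C=C1CCC3C2C(=O)CC4(C)C3CCC4(O)C(=O)CO,decoy
pge2,CCCCCC(O)C=CC1C(O)CC(=O)C1CC=CCCCC(=O)O,decoy
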