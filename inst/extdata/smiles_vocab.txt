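c1ccccc1
Cc1ccccc1
CCc1ccccc1
CCCc1ccccc1
Oc1ccccc1
OCc1ccccc1
Nc1ccccc1
NCc1ccccc1
Fc1ccccc1
Clc1ccccc1
Brc1ccccc1
O=COc1ccccc1
O=CNc1ccccc1
O=COCc1ccccc1
O=[SH](=O)Nc1ccccc1
OCCc1ccccc1
NCCc1ccccc1
O=CCc1ccccc1
O=C(O)Cc1ccccc1
CNCc1ccccc1
COc1ccccc1
CNc1ccccc1
c1ccncc1
Cc1ccncc1
CCc1ccncc1
CCCc1ccncc1
Oc1ccncc1
OCc1ccncc1
Nc1ccncc1
NCc1ccncc1
Fc1ccncc1
Clc1ccncc1
Brc1ccncc1
O=COc1ccncc1
O=CNc1ccncc1
O=COCc1ccncc1
O=[SH](=O)Nc1ccncc1
OCCc1ccncc1
NCCc1ccncc1
O=CCc1ccncc1
O=C(O)Cc1ccncc1
CNCc1ccncc1
COc1ccncc1
CNc1ccncc1
c1ccc2ccccc2c1
Cc1ccc2ccccc2c1
CCc1ccc2ccccc2c1
CCCc1ccc2ccccc2c1
Oc1ccc2ccccc2c1
OCc1ccc2ccccc2c1
Nc1ccc2ccccc2c1
NCc1ccc2ccccc2c1
Fc1ccc2ccccc2c1
Clc1ccc2ccccc2c1
Brc1ccc2ccccc2c1
O=COc1ccc2ccccc2c1
O=CNc1ccc2ccccc2c1
O=COCc1ccc2ccccc2c1
O=[SH](=O)Nc1ccc2ccccc2c1
OCCc1ccc2ccccc2c1
NCCc1ccc2ccccc2c1
O=CCc1ccc2ccccc2c1
O=C(O)Cc1ccc2ccccc2c1
CNCc1ccc2ccccc2c1
COc1ccc2ccccc2c1
CNc1ccc2ccccc2c1
c1ccc(-c2ccccc2)cc1
Cc1ccc(-c2ccccc2)cc1
CCc1ccc(-c2ccccc2)cc1
CCCc1ccc(-c2ccccc2)cc1
Oc1ccc(-c2ccccc2)cc1
OCc1ccc(-c2ccccc2)cc1
Nc1ccc(-c2ccccc2)cc1
NCc1ccc(-c2ccccc2)cc1
Fc1ccc(-c2ccccc2)cc1
Clc1ccc(-c2ccccc2)cc1
Brc1ccc(-c2ccccc2)cc1
O=COc1ccc(-c2ccccc2)cc1
O=CNc1ccc(-c2ccccc2)cc1
O=COCc1ccc(-c2ccccc2)cc1
O=[SH](=O)Nc1ccc(-c2ccccc2)cc1
OCCc1ccc(-c2ccccc2)cc1
NCCc1ccc(-c2ccccc2)cc1
O=CCc1ccc(-c2ccccc2)cc1
O=C(O)Cc1ccc(-c2ccccc2)cc1
CNCc1ccc(-c2ccccc2)cc1
COc1ccc(-c2ccccc2)cc1
CNc1ccc(-c2ccccc2)cc1
c1ccc2[nH]ccc2c1
Cc1ccc2[nH]ccc2c1
CCc1ccc2[nH]ccc2c1
CCCc1ccc2[nH]ccc2c1
Oc1ccc2[nH]ccc2c1
OCc1ccc2[nH]ccc2c1
Nc1ccc2[nH]ccc2c1
NCc1ccc2[nH]ccc2c1
Fc1ccc2[nH]ccc2c1
Clc1ccc2[nH]ccc2c1
Brc1ccc2[nH]ccc2c1
O=COc1ccc2[nH]ccc2c1
O=CNc1ccc2[nH]ccc2c1
O=COCc1ccc2[nH]ccc2c1
O=[SH](=O)Nc1ccc2[nH]ccc2c1
OCCc1ccc2[nH]ccc2c1
NCCc1ccc2[nH]ccc2c1
O=CCc1ccc2[nH]ccc2c1
O=C(O)Cc1ccc2[nH]ccc2c1
CNCc1ccc2[nH]ccc2c1
COc1ccc2[nH]ccc2c1
CNc1ccc2[nH]ccc2c1
C1CCNCC1
CC1CCNCC1
CCC1CCNCC1
CCCC1CCNCC1
OC1CCNCC1
OCC1CCNCC1
NC1CCNCC1
NCC1CCNCC1
FC1CCNCC1
ClC1CCNCC1
BrC1CCNCC1
O=COC1CCNCC1
O=CNC1CCNCC1
O=COCC1CCNCC1
O=[SH](=O)NC1CCNCC1
OCCC1CCNCC1
NCCC1CCNCC1
O=CCC1CCNCC1
O=C(O)CC1CCNCC1
CNCC1CCNCC1
COC1CCNCC1
CNC1CCNCC1
C1CCOCC1
CC1CCOCC1
CCC1CCOCC1
CCCC1CCOCC1
OC1CCOCC1
OCC1CCOCC1
NC1CCOCC1
NCC1CCOCC1
FC1CCOCC1
ClC1CCOCC1
BrC1CCOCC1
O=COC1CCOCC1
O=CNC1CCOCC1
O=COCC1CCOCC1
O=[SH](=O)NC1CCOCC1
OCCC1CCOCC1
NCCC1CCOCC1
O=CCC1CCOCC1
O=C(O)CC1CCOCC1
CNCC1CCOCC1
COC1CCOCC1
CNC1CCOCC1
c1ccc(N2CCNCC2)cc1
Cc1ccc(N2CCNCC2)cc1
CCc1ccc(N2CCNCC2)cc1
CCCc1ccc(N2CCNCC2)cc1
Oc1ccc(N2CCNCC2)cc1
OCc1ccc(N2CCNCC2)cc1
Nc1ccc(N2CCNCC2)cc1
NCc1ccc(N2CCNCC2)cc1
Fc1ccc(N2CCNCC2)cc1
Clc1ccc(N2CCNCC2)cc1
Brc1ccc(N2CCNCC2)cc1
O=COc1ccc(N2CCNCC2)cc1
O=CNc1ccc(N2CCNCC2)cc1
O=COCc1ccc(N2CCNCC2)cc1
O=[SH](=O)Nc1ccc(N2CCNCC2)cc1
OCCc1ccc(N2CCNCC2)cc1
NCCc1ccc(N2CCNCC2)cc1
O=CCc1ccc(N2CCNCC2)cc1
O=C(O)Cc1ccc(N2CCNCC2)cc1
CNCc1ccc(N2CCNCC2)cc1
COc1ccc(N2CCNCC2)cc1
CNc1ccc(N2CCNCC2)cc1
c1ccc2ncccc2c1
Cc1ccc2ncccc2c1
CCc1ccc2ncccc2c1
CCCc1ccc2ncccc2c1
Oc1ccc2ncccc2c1
OCc1ccc2ncccc2c1
Nc1ccc2ncccc2c1
NCc1ccc2ncccc2c1
Fc1ccc2ncccc2c1
Clc1ccc2ncccc2c1
Brc1ccc2ncccc2c1
O=COc1ccc2ncccc2c1
O=CNc1ccc2ncccc2c1
O=COCc1ccc2ncccc2c1
O=[SH](=O)Nc1ccc2ncccc2c1
OCCc1ccc2ncccc2c1
NCCc1ccc2ncccc2c1
O=CCc1ccc2ncccc2c1
O=C(O)Cc1ccc2ncccc2c1
CNCc1ccc2ncccc2c1
COc1ccc2ncccc2c1
CNc1ccc2ncccc2c1
C
CO
CC(=O)O
CN
CC(N)=O
CC#N
CC
CCO
CCC(=O)O
CCN
CCC(N)=O
CCC#N
CCC
CCCO
CCCC(=O)O
CCCN
CCCC(N)=O
CCCC#N
CCCC
CCCCO
CCCCC(=O)O
CCCCN
CCCCC(N)=O
CCCCC#N
CCCCC
CCCCCO
CCCCCC(=O)O
CCCCCN
CCCCCC(N)=O
CCCCCC#N
CCCCCC
CCCCCCO
CCCCCCC(=O)O
CCCCCCN
CCCCCCC(N)=O
CCCCCCC#N
CCCCCCC
CCCCCCCO
CCCCCCCC(=O)O
CCCCCCCN
CCCCCCCC(N)=O
CCCCCCCC#N
CCCCCCCC
CCCCCCCCO
CCCCCCCCC(=O)O
CCCCCCCCN
CCCCCCCCC(N)=O
CCCCCCCCC#N
CC(=O)Oc1ccccc1C(=O)O
CC(=O)Nc1ccc(O)cc1
CN1CCC[C@H]1c1cccnc1
Cn1c(=O)c2c(ncn2C)n(C)c1=O
CC(C)Cc1ccc(C(C)C(=O)O)cc1
O=C(O)c1ccccc1O
Nc1ccc(S(N)(=O)=O)cc1
CCN(CC)CCNC(=O)c1ccc(N)cc1
Clc1ccccc1-c1nc2ccccc2[nH]1
O=C(O)CCc1ccccc1
NCCc1ccc(O)c(O)c1
CC(N)Cc1ccccc1
COc1ccc2cc(CCN)ccc2c1
NCCc1ccc(O)cc1
COc1ccc2[nH]cc(CCNC(C)=O)c2c1
O=c1[nH]cnc2[nH]cnc12
Nc1ncnc2[nH]cnc12
Cc1ccc(S(N)(=O)=O)cc1
OCC(O)CO
OCCN(CCO)CCO
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
CN(C)CCCN1c2ccccc2Sc2ccccc21
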