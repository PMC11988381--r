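name,pattern,precedence,suppresses
urea,"[NX3][CX3](=[OX1])[NX3]",1,
carbamate,"[NX3][CX3](=[OX1])[OX2]",2,
anhydride,"[CX3](=[OX1])[OX2][CX3](=[OX1])",3,
isocyanate,"[NX2]=[CX2]=[OX1]",4,
carboxylic acid,"[CX3](=[OX1])[OX2H1]",5,
sulfonic acid,"[#16X4](=[OX1])(=[OX1])([#6])[OX2H1]",6,
sulfonamide,"[#16X4](=[OX1])(=[OX1])([#6])[NX3]",7,
sulfonate ester,"[#16X4](=[OX1])(=[OX1])([#6])[OX2H0][#6]",8,
sulfone,"[#16X4](=[OX1])(=[OX1])([#6])[#6]",9,
sulfinate ester,"[#16X3](=[OX1])([#6])[OX2H0][#6]",10,
sulfoxide,"[#16X3](=[OX1])([#6])[#6]",11,
ester,"[#6][CX3](=[OX1])[OX2][#6;!$([#6X3]=[OX1])]",12,
amide,"[NX3][CX3](=[OX1])[#6]",13,
nitro,"[$([NX3](=[OX1])=[OX1]),$([NX3+](=[OX1])[OX1-])]",14,
nitrile,"[CX2]#[NX1]",15,
aldehyde,"[#6][CX3H1]=[OX1]",16,
thioketone,"[#6][CX3](=[SX1])[#6]",17,
ketone,"[#6][CX3](=[OX1])[#6]",18,
disulfide,"[SX2][SX2]",19,
thiol,"[#16X2H1]",20,
sulfide,"[#6][SX2;!$([SX2][SX2]);H0][#6]",21,
alcohol,"[OX2H1][#6;!$([#6X3]=[OX1])]",22,
ether,"[OX2;H0]([#6;!$([#6X3]=[OX1])])[#6;!$([#6X3]=[OX1])]",23,
amine,"[NX3;!$([NX3][#6X3]=[OX1]);!$([NX3][#6X3]=[SX1]);!$([NX3][#16]);!$([NX3]~[OX1]);!$([NX3][NX2]=[OX1])]",24,
alkyne,"[CX2]#[CX2]",25,
alkene,"[CX3]=[CX3]",26,
phenyl,"c1ccccc1",27,
halide,"[#6][F,Cl,Br,I]",28,
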