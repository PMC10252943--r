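subclass,ion_mode,oxidation,n
TG,positive,none,345
TG,positive,long_chain_O,16
TG,positive,CHO,16
TG,positive,COOH,8
TG,positive,COOCH3,2
DG,positive,none,9
DG,positive,long_chain_O,1
BisMePA,positive,none,1
PEt,positive,none,1
ChE,positive,none,1
Cer,negative,none,13
Cer,negative,long_chain_O,2
HexCer,negative,none,7
HexCer,negative,long_chain_O,1
MGDG,negative,none,1
LPC,negative,none,1
PC,negative,none,11
SM,negative,none,7
LPE,negative,none,1
PA,negative,none,5
PE,negative,none,15
PI,negative,none,9
PS,negative,none,6
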