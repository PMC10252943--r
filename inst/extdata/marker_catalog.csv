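lipid_id,subclass,ion_mode,oxidation,models,mean_NI,sd_NI,mean_IRR,sd_IRR
Cer (d16:1_24:0),Cer,negative,none,PLS-DA,21.60,2.04,24.30,3.05
Cer (d18:1_23:0),Cer,negative,none,PLS-DA,43.70,2.42,46.20,2.69
Cer (d18:1_24:0),Cer,negative,none,PLS-DA,41.60,1.92,43.90,1.89
Hex1Cer (t35:2),HexCer,negative,none,PLS-DA,82.00,34.00,51.10,39.10
LPC (18:2),LPC,negative,none,PLS-DA,16.20,17.50,3.54,2.80
LPE (18:2),LPE,negative,none,PLS-DA,35.60,22.10,12.70,10.30
PA (16:0_18:2),PA,negative,none,PLS-DA,190.00,33.90,121.00,87.00
PA (18:2_18:2),PA,negative,none,PLS-DA,96.50,19.30,62.30,46.40
PA (18:1_18:2),PA,negative,none,PLS-DA,130.00,25.30,83.10,56.20
PC (18:3_18:3),PC,negative,none,PLS-DA/LDA,22.40,17.20,3.15,3.02
PC (18:3_18:2),PC,negative,none,PLS-DA/LDA,74.40,45.70,22.30,18.30
PC (18:2_18:2),PC,negative,none,PLS-DA,276.00,139.00,119.00,88.20
PC (18:1_18:2),PC,negative,none,PLS-DA,127.00,37.30,82.70,29.30
PE (16:1_18:2),PE,negative,none,PLS-DA/LDA,24.90,10.80,11.80,5.29
PE (16:0_18:3),PE,negative,none,PLS-DA/LDA,38.30,20.60,16.00,4.55
PE (16:1_18:1),PE,negative,none,PLS-DA,52.70,14.80,42.30,9.12
PE (16:0_18:2),PE,negative,none,PLS-DA,273.00,91.20,178.00,50.00
PE (18:3_18:3),PE,negative,none,PLS-DA/LDA,11.40,8.65,1.49,1.31
PE (18:3_18:2),PE,negative,none,PLS-DA/LDA,43.00,26.30,9.87,7.16
PE (18:2_18:2),PE,negative,none,PLS-DA/LDA,146.00,70.30,50.50,34.00
PE (18:1_18:3),PE,negative,none,PLS-DA,45.20,20.40,23.40,2.80
PE (18:1_18:2),PE,negative,none,PLS-DA,204.00,36.30,165.00,17.20
PE (18:0_18:2),PE,negative,none,PLS-DA,145.00,19.00,169.00,26.00
PI (15:0_18:2),PI,negative,none,PLS-DA,12.90,6.14,5.77,4.59
PI (16:0_18:3),PI,negative,none,PLS-DA/LDA,14.70,8.40,4.76,3.78
PI (16:0_18:2),PI,negative,none,PLS-DA/LDA,287.00,121.00,133.00,95.60
PI (18:2_18:2),PI,negative,none,PLS-DA/LDA,23.50,8.64,10.60,8.08
PI (18:1_18:2),PI,negative,none,PLS-DA,25.30,8.74,16.70,6.13
PS (16:0_18:3),PS,negative,none,PLS-DA/LDA,16.00,10.10,1.88,0.98
PS (16:0_18:2),PS,negative,none,PLS-DA/LDA,123.00,55.80,49.80,29.70
DG (8:0_14:0),DG,positive,none,LDA,102.00,23.10,73.30,35.30
DG (10:0_14:0),DG,positive,none,PLS-DA/LDA,135.00,26.10,89.10,42.30
DG (12:0_14:0),DG,positive,none,PLS-DA/LDA,151.00,33.00,96.90,52.00
TG (11:2COOH_14:1_15:1),TG,positive,COOH,PLS-DA/LDA,279.00,70.90,173.00,50.30
TG (11:3COOH_14:0_15:1),TG,positive,COOH,PLS-DA/LDA,278.00,72.80,172.00,48.50
TG (11:3COOH_15:1_16:1),TG,positive,COOH,PLS-DA/LDA,200.00,25.90,158.00,30.90
TG (18:1+O_18:1_18:1),TG,positive,long_chain_O,LDA,796.00,158.00,953.00,185.00
TG (18:2+O_18:0_18:0),TG,positive,long_chain_O,PLS-DA/LDA,1080.00,196.00,1280.00,130.00
TG (5:0CHO_12:0_12:0),TG,positive,CHO,PLS-DA/LDA,214.00,57.20,129.00,36.30
TG (5:0CHO_12:0_14:1),TG,positive,CHO,PLS-DA/LDA,72.60,23.10,40.30,12.20
TG (5:0COOH_12:0_12:0),TG,positive,COOH,PLS-DA/LDA,35.60,4.06,24.40,8.35
TG (7:1CHO_12:0_12:0),TG,positive,CHO,PLS-DA/LDA,70.50,22.40,39.60,12.60
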