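"composition","structure","z","mz","ccs_tims","ccs_twims","source","accession"
"HexNAc1","GalNAc-ol",1,222.0983,142.4,142.5,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc1","Gal(b1-3)GalNAc-ol",1,384.1511,184.3,184.7,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc1","Gal(a1-3)GalNAc-ol",1,384.1511,188.3,189,"PGM_synthetic","demo-533-synthetic"
"HexNAc2","GlcNAc(b1-3)GalNAc-ol",1,425.1777,195.7,195.7,"PGM_synthetic","demo-533-synthetic"
"HexNAc2","GlcNAc(b1-6)GalNAc-ol",1,425.1777,199,198.4,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2","Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol",1,587.2305,225.7,225,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2","Gal(b1-3)GlcNAc(b1-3)GalNAc-ol",1,587.2305,228.6,228.6,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2","Gal(b1-4)GlcNAc(b1-3)GalNAc-ol",1,587.2305,232.1,231.7,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc1dHex1","Fuc(a1-2)Gal(b1-3)GalNAc-ol",1,530.209,219.4,218.9,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc1dHex1","",1,530.209,218.8,218.1,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2","Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol",1,749.2833,255.1,254.6,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2","Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",1,749.2833,261.4,261,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2","Gal(b1-3)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",1,749.2833,264.8,265.6,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2dHex1","Fuc(a1-2)Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol",1,733.2884,255.4,255.7,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2dHex1","",1,733.2884,258.8,258.1,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc1NeuAc1","Neu5Ac(a2-3)Gal(b1-3)GalNAc-ol",1,675.2466,244,244.8,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc1NeuAc1","",1,675.2466,250.5,249.7,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2dHex1","Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol",1,895.3412,273,273.5,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2dHex1","Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)[Gal(b1-3)]GalNAc-ol",1,895.3412,275,274.2,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2dHex1","Fuc(a1-2)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",1,895.3412,290,289.1,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2dHex1","Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",1,895.3412,297,297.9,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3","Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)GlcNAc(b1-6)]GalNAc-ol",1,952.3627,291.4,291,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3","",1,952.3627,293.5,293,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3","",1,952.3627,298.7,299.2,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2S1","",1,829.2401,272.4,272.1,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2S1","",1,829.2401,275.6,276.3,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2NeuAc1","Neu5Ac(a2-3)Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol",1,878.3259,281.3,280.6,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2NeuAc1","",1,878.3259,283,282.8,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3dHex1","",1,1098.4206,311.5,311.4,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3dHex1","",1,1098.4206,315.4,315.7,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3dHex1","",1,1098.4206,318.4,319.1,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2dHex2","",1,1041.3991,304.9,304.4,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2dHex2","",1,1041.3991,307.4,306.4,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2dHex1S1","",1,813.2452,270.5,270.5,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc2dHex1S1","",1,813.2452,273.9,273.6,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2NeuAc1","",1,1040.3787,304,304.6,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc2NeuAc1","",1,1040.3787,309.2,308.3,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc3","",1,1114.4155,314.7,314.7,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc3","",1,1114.4155,318.2,318.9,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3S1","",1,1032.3195,304.8,304.5,"PGM_synthetic","demo-533-synthetic"
"Hex2HexNAc3S1","",1,1032.3195,305.3,305.4,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc3dHex1","",1,1260.4734,336.6,337.7,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc3dHex1","",1,1260.4734,341,340,"PGM_synthetic","demo-533-synthetic"
"Hex1HexNAc1NeuAc2","",1,966.342,297.1,296.5,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc3dHex2","",1,1406.5313,355.9,355.2,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc3dHex2","",1,1406.5313,358.6,358.4,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc4","",1,1317.4949,343,341.8,"PGM_synthetic","demo-533-synthetic"
"Hex4HexNAc4dHex1","",1,1625.6056,384.2,385,"PGM_synthetic","demo-533-synthetic"
"Hex3HexNAc4dHex2","",1,1609.6107,381.4,381.3,"PGM_synthetic","demo-533-synthetic"
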