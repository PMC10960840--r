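"species","mz","z","measured","reference_ccs"
"Hex2",341.1089,1,0.71531,175.72
"Hex3",503.1618,1,0.87911,213.31
"Hex4",665.2146,1,1.0171,245.21
"Hex5",827.2674,1,1.13857,273.41
"Hex6",989.3202,1,1.24833,298.96
"Hex7",1151.3731,1,1.34921,322.49
"Hex8",1313.4259,1,1.44307,344.42
"Hex9",1475.4787,1,1.53119,365.04
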