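# Synthetic stand-in for the per-locality lateral-arm-plate summary table
# (locality plate counts, mean areas in mm^2, sample SDs).  Locality names,
# stratigraphic order and qualitative magnitudes (a step decrease at each
# of the three events, a ~4x drop at Mulde, a single very large plate at
# Hoburgen, >1300 specimens in total) follow the published narrative; the
# numbers themselves are invented and fixed once.
locality,age_ma,stage,n,mean,sd
Ireviken,432.8,Telychian,150,0.62,0.16
Lickershamn,431.9,Sheinwoodian,180,0.36,0.10
Brissund,430.8,Sheinwoodian,90,0.40,0.11
Tjalderviken,429.2,Homerian,120,0.48,0.13
Svarvare,428.4,Homerian,160,0.52,0.14
Mulde Tegelbruk,427.8,Homerian,310,0.13,0.04
Gannor,425.2,Ludfordian,140,0.33,0.09
Lau backar,424.6,Ludfordian,90,0.17,0.05
Petsarve,424.1,Ludfordian,80,0.19,0.06
Hoburgen,423.2,Ludfordian,1,1.10,NA
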