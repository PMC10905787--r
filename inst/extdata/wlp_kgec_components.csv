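component_id,name,mw
WLP161,(-)-Epoxycaryophyllene,220.35
WLP9,(+/-)-Isoborneol,154.25
WLP226,(1R)-2-methyl-1-phenylprop-2-en-1-ol,148.2
WLP152,"(1R,4R)-4-isopropyl-1,6-dimethyltetralin",202.34
WLP172,"(Z,Z)-farnesol",222.37
WLP249,1h-indole-3-carboxylic acid,161.16
WLP255,2-lauroleic acid,198.3
WLP221,Akridin,179.22
WLP232,alisol B,444.65
WLP228,alpha-humulene,204.35
WLP175,BOX,122.12
WLP2,DIBP,278.34
WLP206,DTY,181.19
WLP253,Ethyl glucoside,208.21
WLP168,eugenol,164.2
WLP217,LPG,89.09
WLP171,Methylcinnamate,162.19
WLP230,NCA,122.12
WLP218,PHA,165.19
WLP194,PHB,138.12
WLP264,polyporusterone c,476.65
WLP193,protocatechuic acid,154.12
WLP179,Safrol,162.19
WLP219,Scopoletol,192.17
WLP254,Undekansaeure,186.29
WLP204,uridine,244.2
WLP209,GLY,75.07
WLP208,Glutamine,147.13
WLP163,HCI,150.17
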