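herb	herb_name	components	active
GZ	Cinnamomum cassia Presl	220	194
BZ	Atractylodes macrocephala Koidz.	55	43
ZX	Alisma plantago-aquatica Linn.	46	23
FL	Poria Cocos (Schw.) Wolf.	34	7
ZL	Polyporus umbellatus (Pers.) Fries	31	9
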