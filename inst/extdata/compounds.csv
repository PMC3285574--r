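name,charge_class,logPn,logPd,pKa,z,mw
MTR,permanent_cation,,0.16,,1,531.5
Hoe,monoprotic_base,4.49,,7.8,1,452.6
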