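# Synthetic reconstruction of a multichannel compound potency table for the
# three reference compounds (pore-block model: IC50 in uM, Hill coefficient,
# maximal effective free therapeutic plasma concentration in uM).
# Anchored entries (published in the main text of the source studies):
#   verapamil ICaL IC50 0.2 uM / Hill 0.8
#   quinidine IKr  IC50 0.72 uM / Hill 1.06
# All other rows are representative values recalled from public multichannel
# screening datasets and are synthetic in the sense that they were not
# transcribed from the original supplementary table.
compound,current,ic50_uM,hill,eftpc_uM
dofetilide,IKr,0.03,0.9,0.002
verapamil,ICaL,0.2,0.8,0.081
verapamil,IKr,0.288,1.0,0.081
quinidine,IKr,0.72,1.06,0.924
quinidine,INa,16.6,1.0,0.924
quinidine,ICaL,15.6,1.0,0.924
quinidine,Ito,3.5,1.0,0.924
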