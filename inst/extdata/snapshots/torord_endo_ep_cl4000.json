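{
  "state_version": 1,
  "variant": "torord",
  "celltype": "endo",
  "coupled": false,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "h", "j", "hp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "ffp", "fcafp", "nca_ss", "nca_i", "ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i", "xs1", "xs2", "jrel_np", "jrel_p", "camk_trap", "qca"],
  "values": [-87.449066527892, 9.51884912196688, 9.51907968376074, 137.603322522246, 137.603315700287, 6.67238126926922e-05, 5.94605711777528e-05, 1.21425873875448, 1.21611017794649, 0.00106854571311509, 0.800516953569867, 0.800515106762051, 0.626032817664585, 0.800514287820521, 0.000209104554307833, 0.494619661889244, 0.299222141246971, 0.00103910279900715, 0.999508946013893, 0.986633640505261, 0.000529460803022706, 0.999508946131207, 0.992595071452008, 0, 0.999999989404535, 0.997165199913376, 0.999999989404536, 0.999999989404184, 0.999999999983845, 0.999999989404489, 0.999999989404492, 0.000347316854542234, 0.000542916247079266, 0.997254930631758, 0.000933846444780078, 0.000754383356043646, 0.000160788832828339, 6.05073611568084e-06, 0.0415380537087964, 0.00020509539579979, 2.96439387504748e-323, 4.26618181012338e-279, 0.000852671772219425, -0.0317526957222467],
  "metadata": {
    "cl": 4000,
    "protocol": "pre-paced to convergence criterion",
    "beats": 520,
    "converged": true
  }
}
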