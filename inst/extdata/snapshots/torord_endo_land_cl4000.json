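{
  "state_version": 1,
  "variant": "torord",
  "celltype": "endo",
  "coupled": true,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "h", "j", "hp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "ffp", "fcafp", "nca_ss", "nca_i", "ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i", "xs1", "xs2", "jrel_np", "jrel_p", "camk_trap", "xs", "xw", "catrpn", "blocked", "zeta_s", "zeta_w", "qca"],
  "values": [-81.8174126642461, 7.95545449362029, 7.95566452799358, 110.96501234891, 110.965005440257, 6.44742503810931e-05, 5.78715707041185e-05, 1.1697144805405, 1.17132638013256, 0.00351769362878697, 0.638869914454618, 0.63886649517614, 0.409299996312442, 0.638865122374044, 0.000609279497503975, 0.31569931203184, 0.167598595165494, 0.00151873997092325, 0.998684680109934, 0.979818139416966, 0.000774035725793568, 0.998684680283311, 0.985552836023005, 0, 0.999999951374821, 0.99693585322263, 0.999999951374828, 0.999999951373502, 0.999999999878583, 0.999999951374642, 0.999999951374661, 0.000312626761772641, 0.000475417735501041, 0.996204122748697, 0.00139334070009369, 0.001125573683096, 0.000368281848959265, 1.86810239575707e-05, 0.0438910177652584, 0.000385213630987841, 2.96439387504748e-323, 1.27739420628231e-278, 0.000800393344310577, 8.87822871492193e-05, 0.000133130864256922, 0.0063742189892613, 0.999644960384207, 0, 0, -0.0364515999483848],
  "metadata": {
    "cl": 4000,
    "protocol": "pre-paced to convergence criterion",
    "converged": false
  }
}
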