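{
  "state_version": 1,
  "variant": "torord",
  "celltype": "mid",
  "coupled": true,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "h", "j", "hp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "ffp", "fcafp", "nca_ss", "nca_i", "ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i", "xs1", "xs2", "jrel_np", "jrel_p", "camk_trap", "xs", "xw", "catrpn", "blocked", "zeta_s", "zeta_w", "qca"],
  "values": [-89.0669713600062, 14.8510009711857, 14.8515006371388, 142.389732525326, 142.389671185662, 7.8753874727356e-05, 6.36533177841129e-05, 1.91072969523801, 1.91628727831781, 0.000754810691368433, 0.83455351563958, 0.834587134241992, 0.680505465525807, 0.834181102789796, 0.00015378214439363, 0.529614177009223, 0.279329717270276, 0.000931734022705488, 0.999630071479509, 0.557352017381158, 0.000474727467196602, 0.999630068136696, 0.615921781306786, -6.83148662339562e-80, 0.999999993161448, 0.916192901164916, 0.999999993161426, 0.999740717621999, 0.999972613132583, 0.999999993162488, 0.999999993162435, 0.000452327568984066, 0.0010287950574196, 0.996916650901889, 0.000832024842974681, 0.000705665125657463, 0.000633575502705821, 2.20836276077592e-05, 0.268936342668902, 0.000171095842313592, 4.00385459071408e-70, 6.7922680379487e-57, 0.0190542471529534, 0.000138451063164611, 0.000207973431632151, 0.0094710890517345, 0.999445479009223, 0, 0, 0.0373152635125234],
  "metadata": {
    "cl": 1000,
    "protocol": "pre-paced to convergence criterion",
    "beats": 630,
    "converged": true
  }
}
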