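{
  "state_version": 1,
  "variant": "torord",
  "celltype": "endo",
  "coupled": true,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "h", "j", "hp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "ffp", "fcafp", "nca_ss", "nca_i", "ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i", "xs1", "xs2", "jrel_np", "jrel_p", "camk_trap", "xs", "xw", "catrpn", "blocked", "zeta_s", "zeta_w", "qca"],
  "values": [-88.936306569259, 11.9741756803301, 11.9744932170493, 142.884131266182, 142.884090482391, 7.23461834741638e-05, 6.31165890725205e-05, 1.5202127576322, 1.52146452582208, 0.000776352306450139, 0.831997975883888, 0.832031781403362, 0.676295913839697, 0.831864507790735, 0.000157646539156053, 0.5327201330069, 0.29410001113549, 0.000939978067464683, 0.99962150721905, 0.596284437077891, 0.000478929825898761, 0.999621504644454, 0.658887127363307, -2.11687806822408e-85, 0.999999992915184, 0.940715931102859, 0.999999992915167, 0.999901667292465, 0.999985395424526, 0.999999992916001, 0.999999992915959, 0.000437726915837126, 0.000741987958304063, 0.997219782767615, 0.000839988732709099, 0.00069278135106658, 0.000345350228590634, 1.20969214918915e-05, 0.238969094945585, 0.000173622753596213, 6.81282451709359e-77, 2.87478582608802e-62, 0.0108937884432918, 0.000114224196310743, 0.00017204145042713, 0.00800548059274262, 0.999541604557052, 0, 0, -0.000888623192078719],
  "metadata": {
    "cl": 1000,
    "protocol": "pre-paced to convergence criterion",
    "beats": 420,
    "converged": true
  }
}
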