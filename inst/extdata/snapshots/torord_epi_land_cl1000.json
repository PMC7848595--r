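{
  "state_version": 1,
  "variant": "torord",
  "celltype": "epi",
  "coupled": true,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "h", "j", "hp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "ffp", "fcafp", "nca_ss", "nca_i", "ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i", "xs1", "xs2", "jrel_np", "jrel_p", "camk_trap", "xs", "xw", "catrpn", "blocked", "zeta_s", "zeta_w", "qca"],
  "values": [-89.1500517307629, 12.7185491062451, 12.7188503166595, 142.838755531449, 142.838707672285, 6.48065539794879e-05, 5.63885726747705e-05, 1.78338187655695, 1.78385384748914, 0.000741421512143421, 0.83615935523416, 0.836195631500521, 0.683160802658125, 0.836099213318402, 0.000151374458176001, 0.541851325566066, 0.306107753810664, 0.000926530773677274, 0.999635388878211, 0.999633127466425, 0.000472075155726293, 0.999635388701642, 0.999635203636284, 1.44550132626814e-87, 0.999999993313288, 0.949465007546212, 0.999999993313272, 0.999935163743095, 0.999988486129974, 0.999999993314064, 0.999999993314024, 0.000282559228524981, 0.000484869982218528, 0.997329695506637, 0.000827368125477525, 0.000677713563990871, 0.000266019663286275, 9.20314252539941e-06, 0.22543811691025, 0.000169517908286091, 1.06269076874213e-79, 1.08431045089406e-64, 0.0125574224130413, 8.90502079527719e-05, 0.000134345333520478, 0.00643197373017975, 0.999642163501889, 0, 0, 0.0244284542107021],
  "metadata": {
    "cl": 1000,
    "protocol": "pre-paced to convergence criterion",
    "beats": 540,
    "converged": true
  }
}
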