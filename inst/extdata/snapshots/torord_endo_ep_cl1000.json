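{
  "state_version": 1,
  "variant": "torord",
  "celltype": "endo",
  "coupled": false,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "h", "j", "hp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "ffp", "fcafp", "nca_ss", "nca_i", "ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i", "xs1", "xs2", "jrel_np", "jrel_p", "camk_trap", "qca"],
  "values": [-88.9101913795836, 12.0800148673286, 12.0803492088229, 142.667734299256, 142.667691610805, 7.41101995431104e-05, 6.47094247800148e-05, 1.51475036623345, 1.51233048620185, 0.000780729859000094, 0.831469571573275, 0.831282109339841, 0.675427982142544, 0.830921946284288, 0.000158430467405335, 0.529762471651752, 0.290258202408867, 0.000941641169504914, 0.999619698637744, 0.594825326527479, 0.000479777587589679, 0.999619706332855, 0.655641291806389, -1.40819612436816e-84, 0.999999992862821, 0.939842869205744, 0.999999992862873, 0.999902499109499, 0.999984571539241, 0.999999992860139, 0.99999999286029, 0.000482395771504617, 0.000814697937334473, 0.997199126893591, 0.000841539633915043, 0.000695087477105865, 0.000361561395317652, 1.26846015057987e-05, 0.245027380580278, 0.000174213443299034, 9.01448086035875e-77, 3.71477250320305e-62, 0.0107648174789617, -0.000713874286525357],
  "metadata": {
    "cl": 1000,
    "protocol": "pre-paced to convergence criterion",
    "beats": 360,
    "converged": true
  }
}
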