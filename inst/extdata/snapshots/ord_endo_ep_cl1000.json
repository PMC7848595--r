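{
  "state_version": 1,
  "variant": "ord",
  "celltype": "endo",
  "coupled": false,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp", "xrf", "xrs", "xs1", "xs2", "xk1", "jrel_np", "jrel_p", "camk_trap", "qca"],
  "values": [-87.9470948286446, 7.47744222093012, 7.47753107767589, 144.443208968948, 144.443179060466, 8.63276065905876e-05, 8.51983461856969e-05, 1.63384535996301, 1.58685990893091, 0.00738471116132066, 0.69620586224498, 0.696193631019913, 0.696125198411163, 0.452736586829517, 0.696079327745294, 0.000190231790754817, 0.500559124223881, 0.27092289337074, 0.0010048017031696, 0.999549895570776, 0.592621726339455, 0.000511974520584542, 0.999549900953893, 0.645610335650727, 2.37131011697329e-09, 0.999999990738977, 0.909553721514851, 0.999999990739023, 0.999816657947442, 0.999976819057464, 0.00278274628835302, 0.999999990736876, 0.999999990737002, 8.12792661560124e-06, 0.448777306275087, 0.271227752206431, 0.000194017736623489, 0.996774016512969, 2.65546133629801e-07, 3.3176794781381e-07, 0.0128081084650101, 0.0408112992927998],
  "metadata": {
    "cl": 1000,
    "protocol": "pre-paced to convergence criterion",
    "beats": 680,
    "converged": true
  }
}
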