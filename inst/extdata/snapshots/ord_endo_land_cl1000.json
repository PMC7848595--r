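{
  "state_version": 1,
  "variant": "ord",
  "celltype": "endo",
  "coupled": true,
  "names": ["v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp", "xrf", "xrs", "xs1", "xs2", "xk1", "jrel_np", "jrel_p", "camk_trap", "xs", "xw", "catrpn", "blocked", "zeta_s", "zeta_w", "qca"],
  "values": [-87.9677090227289, 7.41451177785884, 7.41458842653783, 144.507159961249, 144.507130428634, 7.84730463716038e-05, 7.68323790132307e-05, 1.62194731097236, 1.58846775539266, 0.00736941787256242, 0.696921943649334, 0.696921649720845, 0.696917889911426, 0.453620032362923, 0.696913116114186, 0.000189488379587692, 0.501832461291481, 0.272150992850141, 0.00100340303342507, 0.999551556590284, 0.593519958742169, 0.000511261508218087, 0.999551556762784, 0.646792650436758, 2.3597587986227e-09, 0.999999990791735, 0.910077978221329, 0.999999990791737, 0.999819343638809, 0.999977662095106, 0.00186969680526846, 0.999999990791644, 0.99999999079165, 8.09708836889599e-06, 0.447954163942258, 0.268266936138016, 0.000193528948346985, 0.996768355668427, 2.65281913902613e-07, 3.31476668718856e-07, 0.0128101440426243, 0.000138508946489592, 0.000206656384345608, 0.00941141095758159, 0.99944816135018, 0, 0, 0.0402855565373349],
  "metadata": {
    "cl": 1000,
    "protocol": "pre-paced to convergence criterion",
    "beats": 740,
    "converged": true
  }
}
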