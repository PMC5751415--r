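{
  "format": "cgbsa-top-1",
  "atoms": [
    {
      "name": "R1",
      "charge": 0.583800059885541,
      "rmin_half": 1.84987482407596,
      "epsilon": 0.0556146549293771,
      "gb_radius": 1.80941910366528,
      "vdw_radius": 1.77091073207557,
      "p1": 0.626595369633287,
      "p2": -0.195701120398007,
      "p3": -0.00624510035384446,
      "p4": 0.000775823362637311,
      "gb_screen": 0.8
    },
    {
      "name": "R2",
      "charge": 0.718775328705876,
      "rmin_half": 1.60220024406444,
      "epsilon": 0.196030987065751,
      "gb_radius": 1.66671360563487,
      "vdw_radius": 1.56850573215634,
      "p1": 0.739875887427479,
      "p2": -0.185952090588398,
      "p3": -0.00485592291690409,
      "p4": 0.000563646841561422,
      "gb_screen": 0.8
    },
    {
      "name": "R3",
      "charge": -0.0267784180682429,
      "rmin_half": 1.6622976918472,
      "epsilon": 0.11476268733386,
      "gb_radius": 1.67337412410416,
      "vdw_radius": 1.60443518552929,
      "p1": 0.475789574161172,
      "p2": -0.178361458494328,
      "p3": -0.00998429445782676,
      "p4": 0.000233703398611397,
      "gb_screen": 0.8
    },
    {
      "name": "R4",
      "charge": 0.703854631137112,
      "rmin_half": 1.8719804223394,
      "epsilon": 0.193636489496566,
      "gb_radius": 1.69924270571209,
      "vdw_radius": 1.70576517386362,
      "p1": 0.508514645881951,
      "p2": -0.152060143579729,
      "p3": -0.00418395997490734,
      "p4": 8.99805163498968e-05,
      "gb_screen": 0.8
    },
    {
      "name": "R5",
      "charge": 0.0203483983397143,
      "rmin_half": 1.78353359303437,
      "epsilon": 0.183163235825486,
      "gb_radius": 1.89234638784546,
      "vdw_radius": 1.77024290980771,
      "p1": 0.731263394095004,
      "p2": -0.180258965771645,
      "p3": -0.00842094791820273,
      "p4": 8.56120649259538e-05,
      "gb_screen": 0.8
    },
    {
      "name": "L1",
      "charge": -0.990010336534993,
      "rmin_half": 1.71386777216103,
      "epsilon": 0.145996815420222,
      "gb_radius": 1.51946824556217,
      "vdw_radius": 1.89312687916681,
      "p1": 0.677281928155571,
      "p2": -0.128064416232519,
      "p3": -0.00640971694141626,
      "p4": 0.000305218369467184,
      "gb_screen": 0.8
    },
    {
      "name": "L2",
      "charge": -1.00998966346501,
      "rmin_half": 1.73073147549294,
      "epsilon": 0.195644991553854,
      "gb_radius": 1.87439769308548,
      "vdw_radius": 1.80381770702079,
      "p1": 0.49621789585799,
      "p2": -0.199211526126601,
      "p3": -0.00354368121596053,
      "p4": 0.000667426514672115,
      "gb_screen": 0.8
    }
  ],
  "bonds": [
    {
      "i": 1,
      "j": 2,
      "k_b": 300,
      "r0": 3.02026001328253
    },
    {
      "i": 2,
      "j": 3,
      "k_b": 300,
      "r0": 4.2983890701099
    },
    {
      "i": 3,
      "j": 4,
      "k_b": 300,
      "r0": 3.36607743056482
    },
    {
      "i": 4,
      "j": 5,
      "k_b": 300,
      "r0": 5.317897458694
    },
    {
      "i": 6,
      "j": 7,
      "k_b": 300,
      "r0": 3.1460463544968
    }
  ],
  "angles": [
    {
      "i": 1,
      "j": 2,
      "k": 3,
      "k_theta": 50,
      "theta0": 0.709160297873966
    },
    {
      "i": 2,
      "j": 3,
      "k": 4,
      "k_theta": 50,
      "theta0": 0.758267235719387
    },
    {
      "i": 3,
      "j": 4,
      "k": 5,
      "k_theta": 50,
      "theta0": 0.793014418747352
    }
  ],
  "torsions": [
    {
      "i": 1,
      "j": 2,
      "k": 3,
      "l": 4,
      "v_n": 1,
      "periodicity": 3,
      "phase": 0
    },
    {
      "i": 2,
      "j": 3,
      "k": 4,
      "l": 5,
      "v_n": 1,
      "periodicity": 3,
      "phase": 0
    }
  ],
  "partition": {
    "receptor": [1, 2, 3, 4, 5],
    "ligand": [6, 7]
  }
}
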