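{
 "system": "h2o_dimer",
 "constraint": null,
 "engine": "pyscf 2.12.1",
 "method": "wb97x_d (libxc 471) + CHG-D2 dispersion (geometry only)",
 "basis": "def2-tzvp (spherical)",
 "scf_energy_hartree": -152.88389474872983,
 "n_electrons": 20,
 "optimization": "GAU_TIGHT criteria; last accepted step of the trajectory",
 "note": "virtual orbitals omitted from the Molden file; density-complete for occupied-orbital descriptors",
 "geometry_bohr": {
  "symbols": [
   "O",
   "H",
   "H",
   "O",
   "H",
   "H"
  ],
  "coords": [
   [
    -2.9211184225,
    -0.2069971895,
    0.0
   ],
   [
    -3.6761611558,
    1.4357374674,
    0.0
   ],
   [
    -1.1185165126,
    0.0856059735,
    0.0
   ],
   [
    2.5411027889,
    0.1867080412,
    0.0
   ],
   [
    3.1589866791,
    -0.7132609822,
    -1.4452661625
   ],
   [
    3.1589866791,
    -0.7132609822,
    1.4452661625
   ]
  ]
 }
}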