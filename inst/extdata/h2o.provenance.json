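{
 "system": "h2o",
 "constraint": null,
 "engine": "pyscf 2.12.1",
 "method": "wb97x_d (libxc 471) + CHG-D2 dispersion (geometry only)",
 "basis": "def2-tzvp (spherical)",
 "scf_energy_hartree": -76.43766937372502,
 "n_electrons": 10,
 "optimization": "GAU_TIGHT criteria; last accepted step of the trajectory",
 "note": "virtual orbitals omitted from the Molden file; density-complete for occupied-orbital descriptors",
 "geometry_bohr": {
  "symbols": [
   "O",
   "H",
   "H"
  ],
  "coords": [
   [
    0.0,
    0.0,
    0.3171167424
   ],
   [
    0.0,
    1.4399203943,
    -0.7788992834
   ],
   [
    0.0,
    -1.4399203943,
    -0.7788992834
   ]
  ]
 }
}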