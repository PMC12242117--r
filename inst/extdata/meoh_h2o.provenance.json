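{
 "system": "meoh_h2o",
 "engine": "pyscf 2.12.1",
 "method": "wb97x_d (libxc 471) + CHG-D2 dispersion (geometry only)",
 "basis": "def2-tzvp (spherical)",
 "scf_energy_hartree": -192.17927351328981,
 "n_electrons": 28,
 "optimization": "standard criteria; last accepted step (optimizer stalled at the SCF-grid noise floor, |grad| rms 5e-5)",
 "note": "virtual orbitals omitted from the Molden file; density-complete for occupied-orbital descriptors",
 "geometry_bohr": {
  "symbols": [
   "C",
   "O",
   "H",
   "H",
   "H",
   "H",
   "O",
   "H",
   "H"
  ],
  "coords": [
   [
    -2.803475666,
    0.0365361752,
    0.0
   ],
   [
    -0.126939217,
    -0.0321809393,
    0.0
   ],
   [
    0.4426936721,
    -1.7470734783,
    0.0
   ],
   [
    -3.3432967594,
    2.0210091206,
    0.0
   ],
   [
    -3.5895446147,
    -0.8640484102,
    1.6868316167
   ],
   [
    -3.5895446147,
    -0.8640484102,
    -1.6868316167
   ],
   [
    1.0360428639,
    5.2107161146,
    0.0
   ],
   [
    1.0738377906,
    3.3856674409,
    0.0
   ],
   [
    2.7652827006,
    5.7360360143,
    0.0
   ]
  ]
 }
}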