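{
 "system": "dme_h2o",
 "engine": "pyscf 2.12.1",
 "method": "wb97x_d (libxc 471) + CHG-D2 dispersion (geometry only)",
 "basis": "def2-tzvp (spherical)",
 "scf_energy_hartree": -231.48095295069297,
 "n_electrons": 36,
 "optimization": "standard criteria; last accepted step (optimizer stalled at the SCF-grid noise floor, |grad| rms 4e-5)",
 "note": "virtual orbitals omitted; coefficients below 1e-9 omitted; density-complete for occupied-orbital descriptors",
 "geometry_bohr": {
  "symbols": [
   "O",
   "C",
   "C",
   "H",
   "H",
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
    0.68345084,
    0.2050474288,
    0.0
   ],
   [
    2.6683653579,
    1.9624079453,
    0.0
   ],
   [
    -1.7244912679,
    1.3301925392,
    0.0
   ],
   [
    4.4341180253,
    0.9063988311,
    0.0
   ],
   [
    2.6018285026,
    3.1692309173,
    1.6843000065
   ],
   [
    2.6018285026,
    3.1692309173,
    -1.6843000065
   ],
   [
    -3.1102538821,
    -0.1901008007,
    0.0
   ],
   [
    -1.997938058,
    2.5047237682,
    1.6855520379
   ],
   [
    -1.997938058,
    2.5047237682,
    -1.6855520379
   ],
   [
    -0.3407114101,
    -5.0738785072,
    0.0
   ],
   [
    0.3261588489,
    -3.3736330559,
    0.0
   ],
   [
    1.1008911931,
    -6.1641196455,
    0.0
   ]
  ]
 }
}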