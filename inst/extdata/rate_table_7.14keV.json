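{
  "version": "1.0",
  "photon_energy_keV": 7.14,
  "comment": "Per-element atomic data at 7.14 keV photon energy. photo_xs: total photoabsorption cross section of the neutral atom (A^2), from standard photoabsorption tabulations interpolated to 7.14 keV. k_fraction: fraction of the photo cross section due to the K shell. kshell_binding: K-shell binding energy of the neutral (eV). auger_rate: total K-hole decay rate (fs^-1). fluorescence_yield: radiative branching of K-hole decay. auger_energy: mean KLL/KVV Auger electron energy (eV). ionization_energies: successive ionization energies (eV), entry q+1 is the energy to go from charge state q to q+1.",
  "elements": {
    "H": {
      "Z": 1, "mass": 1.008,
      "photo_xs": 7.0e-10, "k_fraction": 0.0,
      "kshell_binding": 13.598, "auger_rate": 0.0,
      "fluorescence_yield": 0.0, "auger_energy": 0.0,
      "ionization_energies": [13.598]
    },
    "C": {
      "Z": 6, "mass": 12.011,
      "photo_xs": 5.7e-8, "k_fraction": 0.94,
      "kshell_binding": 288.0, "auger_rate": 0.0935,
      "fluorescence_yield": 0.0028, "auger_energy": 250.0,
      "ionization_energies": [11.260, 24.383, 47.888, 64.494, 392.09, 489.99]
    },
    "N": {
      "Z": 7, "mass": 14.007,
      "photo_xs": 1.2e-7, "k_fraction": 0.95,
      "kshell_binding": 402.0, "auger_rate": 0.141,
      "fluorescence_yield": 0.0052, "auger_energy": 360.0,
      "ionization_energies": [14.534, 29.601, 47.449, 77.474, 97.890, 552.07, 667.05]
    },
    "O": {
      "Z": 8, "mass": 15.999,
      "photo_xs": 2.3e-7, "k_fraction": 0.96,
      "kshell_binding": 532.0, "auger_rate": 0.204,
      "fluorescence_yield": 0.0083, "auger_energy": 468.0,
      "ionization_energies": [13.618, 35.121, 54.936, 77.414, 113.90, 138.12, 739.29, 871.41]
    },
    "S": {
      "Z": 16, "mass": 32.06,
      "photo_xs": 5.6e-6, "k_fraction": 0.90,
      "kshell_binding": 2472.0, "auger_rate": 0.769,
      "fluorescence_yield": 0.078, "auger_energy": 2110.0,
      "ionization_energies": [10.360, 23.338, 34.790, 47.222, 72.595, 88.053, 280.95, 328.75, 379.55, 447.50, 504.80, 564.44, 652.20, 707.01, 3223.78, 3494.19]
    }
  }
}
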