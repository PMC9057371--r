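# Example system file for the edl command-line driver: a 1.5 nm macroion at
# Q = 0.102 C/m^2 in 1 M NaCl + 0.5 M MgCl2 with a 27.75 M hard-sphere
# solvent (diameter ratio 1 : 1.25 : 2 : 1.5 on sigma = 0.2125 nm).
species:
  - {label: Mg,      diameter_nm: 0.2125,   valence: 2,  concentration_M: 0.5}
  - {label: Na,      diameter_nm: 0.265625, valence: 1,  concentration_M: 1.0}
  - {label: Cl,      diameter_nm: 0.425,    valence: -1, concentration_M: 2.0}
  - {label: solvent, diameter_nm: 0.31875,  valence: 0,  concentration_M: 27.75}
macroion: {R_nm: 1.5, Q_C_per_m2: 0.102}
epsilon: 78.5
T_K: 298
seed: 1
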