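# Alkali-cation self parameters of the Madrid-2019 scaled-charge force
# field (Zeron, Abascal & Vega, J. Chem. Phys. 151, 134504, 2019; Li+ from
# the extension in J. Chem. Phys. 156, 044505, 2022): literature
# constants, user-editable. Charges are +0.85 e by construction.
# epsilon_over_kB in K, sigma in angstrom, mass in g/mol.
#
# Ion-water and ion-ion cross terms of Madrid-2019 deviate from
# Lorentz-Berthelot; add them to your own config as 'pairs:' overrides
# (this file carries self terms only, crosses default to LB).
atom_types:
  Li: {charge: 0.85, sigma: 1.439655, epsilon_over_kB: 52.32563, mass: 6.94}
  Na: {charge: 0.85, sigma: 2.21737, epsilon_over_kB: 177.0846, mass: 22.98977}
  K: {charge: 0.85, sigma: 2.30140, epsilon_over_kB: 238.8342, mass: 39.0983}
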