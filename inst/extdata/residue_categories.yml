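# Residue name -> molecular category dictionary (overridable).
# Names are matched case-insensitively after stripping padding.
# Exact-name collisions between ions and one-letter ribonucleotide codes
# (e.g. K) are resolved in favour of water_ions.
protein:
  - ALA
  - ARG
  - ASN
  - ASP
  - CYS
  - GLN
  - GLU
  - GLY
  - HIS
  - ILE
  - LEU
  - LYS
  - MET
  - PHE
  - PRO
  - SER
  - THR
  - TRP
  - TYR
  - VAL
  # protonation / tautomer variants
  - HSD
  - HSE
  - HSP
  - HID
  - HIE
  - HIP
  - LYN
  - GLH
  - ASH
  - CYX
  - CYM
  # terminal caps
  - ACE
  - NME
  - NMA
  - NH2
lipid:
  - POPC
  - POPE
  - POPG
  - POPS
  - DPPC
  - DOPC
  - DOPE
  - DOPS
  - DMPC
  - DLPC
  - DSPC
  - CHOL
  - CHL1
  - PSM
  - POP2
  # Martini codes
  - DPP
  - DOP
  - POP
  - W1PC
  - CDL2
nucleic:
  - DA
  - DT
  - DG
  - DC
  - DU
  - RA
  - RU
  - RG
  - RC
  - A
  - U
  - G
  - C
  - DA5
  - DA3
  - DT5
  - DT3
  - DG5
  - DG3
  - DC5
  - DC3
glucid:
  - GLC
  - GAL
  - MAN
  - NAG
  - NDG
  - BGLC
  - BGAL
  - BMAN
  - FUC
  - XYL
  - SIA
water_ions:
  - SOL
  - WAT
  - HOH
  - TIP3
  - TIP4
  - TIP5
  - SPC
  - SPCE
  - W
  - WF
  - NA
  - CL
  - K
  - MG
  - CA
  - ZN
  - ION
  - NA+
  - CL-
  - K+
  - CA2+
  - SOD
  - CLA
  - POT
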