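# Frozen descriptor manifest: 208 descriptor names, one per line, in feature order.
MW
ExactMass
LogP
MolarRefractivity
TPSA
HBondAcceptors1
HBondAcceptors2
HBondDonors
nAtomC
nAtomN
nAtomO
nAtomS
nAtomP
nAtomF
nAtomCl
nAtomBr
nAtomI
nAtomB
nAtomSi
nAtomOther
nHeavyAtoms
nHydrogens
nHeteroAtoms
nHalogens
fracHeteroAtoms
nPosCharge
nNegCharge
netFormalCharge
nBonds
nSingleBonds
nDoubleBonds
nTripleBonds
nAromaticBonds
nRotatableBonds
nRingBonds
nRingsCyclomatic
nRingAtoms
nAromaticAtoms
nAtomsRing3
nAtomsRing4
nAtomsRing5
nAtomsRing6
nAtomsRing7
nAtomsRing8
fracAromaticAtoms
Chi0
Chi1
Chi2
Chi3
Chi4
Chi0v
Chi1v
Chi2v
Chi3v
Chi4v
Kappa1
Kappa2
Kappa3
WienerIndex
BalabanJ
ZagrebM1
ZagrebM2
PlattF
GraphRadius
GraphDiameter
EccentricConnectivity
PetitjeanShape
HararyIndex
ATS_m_1
ATS_en_1
ATS_r_1
ATS_p_1
ATS_m_2
ATS_en_2
ATS_r_2
ATS_p_2
ATS_m_3
ATS_en_3
ATS_r_3
ATS_p_3
ATS_m_4
ATS_en_4
ATS_r_4
ATS_p_4
ATS_m_5
ATS_en_5
ATS_r_5
ATS_p_5
ATS_m_6
ATS_en_6
ATS_r_6
ATS_p_6
ATS_m_7
ATS_en_7
ATS_r_7
ATS_p_7
ATS_m_8
ATS_en_8
ATS_r_8
ATS_p_8
Moran_m_1
Moran_en_1
Moran_r_1
Moran_p_1
Moran_m_2
Moran_en_2
Moran_r_2
Moran_p_2
Moran_m_3
Moran_en_3
Moran_r_3
Moran_p_3
Moran_m_4
Moran_en_4
Moran_r_4
Moran_p_4
Moran_m_5
Moran_en_5
Moran_r_5
Moran_p_5
Moran_m_6
Moran_en_6
Moran_r_6
Moran_p_6
Moran_m_7
Moran_en_7
Moran_r_7
Moran_p_7
Moran_m_8
Moran_en_8
Moran_r_8
Moran_p_8
Geary_m_1
Geary_en_1
Geary_r_1
Geary_p_1
Geary_m_2
Geary_en_2
Geary_r_2
Geary_p_2
Geary_m_3
Geary_en_3
Geary_r_3
Geary_p_3
Geary_m_4
Geary_en_4
Geary_r_4
Geary_p_4
Geary_m_5
Geary_en_5
Geary_r_5
Geary_p_5
Geary_m_6
Geary_en_6
Geary_r_6
Geary_p_6
Geary_m_7
Geary_en_7
Geary_r_7
Geary_p_7
Geary_m_8
Geary_en_8
Geary_r_8
Geary_p_8
fr_carboxylic_acid
fr_ester
fr_amide
fr_aldehyde
fr_ketone
fr_ether
fr_phenol
fr_aliphatic_alcohol
fr_primary_amine
fr_secondary_amine
fr_tertiary_amine
fr_nitro
fr_nitrile
fr_azo
fr_hydrazine
fr_imine
fr_guanidine
fr_urea
fr_carbamate
fr_thiol
fr_sulfide
fr_disulfide
fr_sulfoxide
fr_sulfone
fr_sulfonamide
fr_phosphoryl
fr_aliphatic_halide
fr_aromatic_halide
fr_alkene
fr_alkyne
fr_benzene
fr_aromatic_N
fr_aromatic_O
fr_aromatic_S
fr_NH_aromatic
fr_epoxide
fr_lactone
fr_lactam
fr_acyl_halide
fr_anhydride
fr_methyl
fr_methylene
fr_quaternary_C
fr_sp2_carbon
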