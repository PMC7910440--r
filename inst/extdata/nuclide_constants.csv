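isotope,element,abundance,atomic_mass,half_life_yr,E_alpha_MeV,E_beta_MeV,E_gamma_MeV,provenance
U238,U,0.992745,238.0508,4.468e9,42.92,2.13,1.78,"abundance/half-life: standard isotopic compilations (CODATA/IUPAC); chain energies: sum over 238U->206Pb series at secular equilibrium, alpha-particle energies, mean beta kinetic energies (antineutrinos excluded), photon energies, from standard decay data (ENSDF-based)"
U235,U,0.007200,235.0439,7.04e8,41.95,1.03,0.57,"abundance/half-life: standard isotopic compilations; chain energies: 235U->207Pb series sum at secular equilibrium, same conventions"
Th232,Th,1.0,232.0381,1.405e10,35.99,1.26,2.40,"Th is mono-isotopic; chain energies: 232Th->208Pb series sum at secular equilibrium (212Bi branch weighted), same conventions"
K40,K,1.17e-4,39.9640,1.248e9,0,0.522,0.157,"abundance 0.0117 atom %; beta = 89.3% branch x 0.585 MeV mean; gamma = 10.7% EC branch x 1.461 MeV"
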