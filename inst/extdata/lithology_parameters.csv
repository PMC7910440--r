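lithology,U_ppm,Th_ppm,K2O_wt_pct,grain_density_g_cm3,phi0_default,provenance
abyssal_clay,2.6,13.4,3.0,2.60,0.83,"pelagic clay averages from standard marine-geochemistry compilations; grain density of terrigenous clay; seafloor porosity typical of abyssal clay (0.80-0.85)"
calcareous_ooze,0.7,1.5,0.5,2.71,0.65,"deep-sea carbonate averages; calcite grain density"
siliceous_ooze,1.2,5.0,1.5,2.10,0.80,"diatom/radiolarian ooze averages; opal-rich grain density"
calcareous_marl,1.7,7.0,1.7,2.68,0.70,"nannofossil-bearing clay: intermediate clay/carbonate mix"
lithogenous,2.8,10.7,2.8,2.65,0.60,"upper continental crust averages; quartz grain density"
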