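medium,radiation,G_mean,G_sd,G_max,n_samples,provenance
pure_water,alpha,1.30,0.13,NA,4,"alpha-irradiated air-saturated deionized water, consistent with cyclotron He2+ yields"
pure_water,gamma,0.45,0.05,NA,4,"gamma-irradiated pure water, standard primary-yield compilations"
seawater,alpha,1.30,0.13,NA,4,"indistinguishable from pure water at 90% confidence"
seawater,gamma,0.45,0.05,NA,4,"indistinguishable from pure water at 90% confidence"
abyssal_clay,alpha,16.90,2.5,35.10,11,"lithology mean = 13x pure water (more than an order of magnitude); per-sample maximum 27x pure water; per-sample rows not recoverable, means only (flagged)"
abyssal_clay,gamma,1.80,0.27,NA,11,"lithology mean = 4x pure water"
siliceous_ooze,alpha,19.50,2.9,NA,3,"lithology mean = 15x pure water (clay-bearing diatom ooze)"
siliceous_ooze,gamma,3.60,0.54,NA,3,"lithology mean = 8x pure water"
calcareous_marl,alpha,15.60,2.3,NA,2,"lithology mean = 12x pure water (nannofossil-bearing clay)"
calcareous_marl,gamma,0.90,0.14,NA,2,"lithology mean = 2x pure water"
calcareous_ooze,alpha,6.50,1.0,NA,2,"lithology mean = 5x pure water"
calcareous_ooze,gamma,0.90,0.14,NA,2,"lithology mean = 2x pure water"
lithogenous,alpha,6.50,1.0,NA,2,"no printed lithology factor; approximate ooze-like amplification (5x) assigned, overridable"
lithogenous,gamma,0.90,0.14,NA,2,"no printed lithology factor; approximate amplification (2x) assigned, overridable"
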