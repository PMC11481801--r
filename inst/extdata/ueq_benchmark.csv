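scale,excellent,good,above_average,below_average
attractiveness,1.75,1.52,1.17,0.70
perspicuity,1.90,1.56,1.08,0.64
efficiency,1.78,1.47,0.98,0.54
dependability,1.65,1.48,1.14,0.78
stimulation,1.55,1.31,0.99,0.50
novelty,1.40,1.05,0.71,0.30
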