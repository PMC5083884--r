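species,source,family,a,b,r_squared,sampling_days
Picea abies,measured,power,0.00002,1.8344,0.93,15;21;28;42
Picea abies,greenness,power,0.00004,1.5931,0.77,15;21;28;42
Pinus sylvestris,measured,power,0.00003,1.8447,0.88,14;21;28;42
Pinus sylvestris,greenness,power,0.00004,1.7889,0.93,14;21;28;42
Fagus sylvatica,measured,power,0.0009,1.6366,0.95,21;28;35;42
Fagus sylvatica,greenness,log,0.1384,-0.2741,0.67,21;28;35;42
Fagus sylvatica,height,power,0.0012,1.5317,0.77,21;28;35;42
Quercus ilex,measured,power,0.00007,2.2141,0.92,21;30;40;49
Quercus ilex,greenness,log,0.3118,-0.884,0.95,21;30;40;49
Quercus ilex,height,power,0.0005,1.6824,0.69,21;30;40;49
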