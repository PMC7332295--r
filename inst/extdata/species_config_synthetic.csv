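species,culmen_length_m,culmen_to_body_ratio,size_class,airspeed_low,airspeed_high
common_murre,0.045,0.1046511627906977,large,13.32,24.68
horned_puffin,0.038,0.1151515151515152,medium,13.95,18.65
pigeon_guillemot,0.030,0.09375,medium,13.95,18.65
tufted_puffin,0.040,0.1052631578947368,medium,13.95,18.65
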