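# Consumption profiles for single-commodity (strawberry) dietary exposure.
# NL toddler: EU PRIMo subgroup, 8-20 months; body weight 10.20 kg, large
# portion 166.70 g/day, mean strawberry consumption 0.344 g/kg bw/day.
# Unit weight 15 g (single strawberry, < 25 g => IESTI Case 1).
label,body_weight_kg,large_portion_g_day,mean_consumption_g_kgbw_day,unit_weight_g,processing_factor,conversion_factor,variability_factor
NL toddler,10.20,166.70,0.344,15,1,1,1
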