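quantity,value
total_reported_mass_kg,190407
scales_mass_kg,190404
n_records,80
n_records_with_mass,77
identified_sorted_mass_kg,291
n_sacks_sampled,67
total_sack_mass_kg,2475
n_single_species_wb_sacks,43
n_single_species_bb_sacks,3
n_mixed_sacks,21
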