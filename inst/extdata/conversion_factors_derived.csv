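# Mass-to-individual conversion factors (kg of dried scales + claws per
# individual). DERIVED values: the primary factors are not published in the
# main text, so these are back-derived as estimated-mass / MNI from the
# published per-group estimates. n is the number of individuals behind the
# white- and black-bellied means; the Smutsia value is the mean of the giant
# ground and Temminck's factors (n not reported).
group,cf_kg,n
white_bellied,0.1773798268,7
black_bellied,0.1989103524,6
smutsia,2.9349396516,NA
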