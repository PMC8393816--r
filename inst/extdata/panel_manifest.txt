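Default analyte panel (generated by default_panel())
total_analytes	226
lipid_species	207
carnitines	19
carnitine:long	9
carnitine:short	10
PC:aa	50
PC:ae	50
PC:lyso	7
PE:aa	42
PE:ae	43
PE:lyso	9
PG:aa	6
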