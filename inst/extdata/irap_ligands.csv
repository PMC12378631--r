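ligand_id,formula,ic50_nM,expected_mplus_h
HA08,,18,
cmpd28,C27H35N4O6S2,,575.1998
cmpd29,C27H35N4O6S2,,575.1998
cmpd30,C26H33N4O7S2,,571.1791
cmpd31,C26H33N4O7S2,,577.1791
cmpd32,C27H36N5O5S2,,574.2158
cmpd33,C33H40N5O5S2,,650.2471
cmpd34,C25H33N4O5S2,59,533.1892
cmpd35,C24H35N4O6S2,,539.1998
cmpd36,C22H33N4O6S2,,513.1842
cmpd37,C25H31N4O6S2,64,547.1685
cmpd38,C25H31N4O6S2,906,547.1685
cmpd39,C25H31N4O6S2,2950,547.1685
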