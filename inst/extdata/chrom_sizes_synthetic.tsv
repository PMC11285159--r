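# SYNTHETIC chromosome-size table approximating the cichlid reference
# karyotype (22 anchored linkage groups; LG21 does not exist in this
# numbering). Sizes are in bp, chosen so the anchored genome is 780 Mb
# (7,800 windows of 100 kb) and LG7 is ~2x the mean of the remaining LGs.
# The unpaired B chromosome carries the mean chromosome size and is not
# anchored (no windows are tiled on it); it participates only in the
# size-weighted Monte Carlo null. Replace with real assembly lengths for
# analyses of real data.
chrom	length	anchored
LG01	37400000	TRUE
LG02	34700000	TRUE
LG03	35500000	TRUE
LG04	33600000	TRUE
LG05	37900000	TRUE
LG06	33100000	TRUE
LG07	67800000	TRUE
LG08	25400000	TRUE
LG09	33800000	TRUE
LG10	31600000	TRUE
LG11	35400000	TRUE
LG12	35600000	TRUE
LG13	32100000	TRUE
LG14	36000000	TRUE
LG15	37600000	TRUE
LG16	34800000	TRUE
LG17	37900000	TRUE
LG18	30800000	TRUE
LG19	30000000	TRUE
LG20	31100000	TRUE
LG22	34100000	TRUE
LG23	33800000	TRUE
B	35500000	FALSE
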