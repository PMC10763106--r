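# Mapping from the 12-plex plasma cytokine assay markers (CSV column names,
# ASCII) to model node names. Identity except IL12p70 -> IL12.
IL1b: IL1b
IL2: IL2
IL4: IL4
IL6: IL6
IL8: IL8
IL10: IL10
IL12p70: IL12
IL13: IL13
IL17: IL17
IL23: IL23
IFNg: IFNg
TNFa: TNFa
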