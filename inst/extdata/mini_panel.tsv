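source	observed
glc__D_e	TRUE
sbt__D_e	TRUE
xyl__D_e	TRUE
glyc_e	FALSE
gentbio_e	TRUE
abt__D_e	TRUE
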