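# Glucose-limited anaerobic scenario, PEP:PTS transport only, FVA at 99%
# of the maximum growth rate.
substrate: EX_glc__D_e
q_s: 10
fva_fraction: 0.99
transporter: pts
co2_fraction: 1
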