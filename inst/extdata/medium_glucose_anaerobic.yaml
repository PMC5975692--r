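# Anaerobic defined medium: glucose sole carbon source, CO2 and inorganics
# unconstrained, auxotrophic amino acids supplied, glutamate capped.
medium:
  EX_glc__D_e: [-10, 0]
  EX_co2_e: [unconstrained, 1000]
  EX_h_e: [unconstrained, 1000]
  EX_h2o_e: [unconstrained, 1000]
  EX_pi_e: [unconstrained, 1000]
  EX_nh4_e: [unconstrained, 1000]
  EX_cys__L_e: [unconstrained, 1000]
  EX_met__L_e: [unconstrained, 1000]
  EX_glu__L_e: [-1, 1000]
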