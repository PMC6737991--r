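# ricenm packaged fixture: fertilizer products and average farmgate
# prices (US$/kg) used in the Odisha on-farm trials
name,grade_n,grade_p2o5,grade_k2o,price_usd_per_kg
urea,46,0,0,0.09
MOP,0,0,60,0.26
DAP,18,46,0,0.38
SSP,0,16,0,0.14
zinc_sulfate,0,0,0,1.08
NP_28_28_0,28,28,0,0.38
NP_20_20_0,20,20,0,0.44
NPK_10_26_26,10,26,26,0.36
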