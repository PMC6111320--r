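pair	pcc	ci_low	ci_up
RG, HR	0.7296	0.6909	0.7642
RG, TA	0.5753	0.5206	0.6253
RG, SC	0.3293	0.2579	0.3972
HR, TA	0.8338	0.8083	0.8561
HR, SC	0.6327	0.5834	0.6773
TA, SC	0.4632	0.3995	0.5224
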