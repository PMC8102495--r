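group,f_over_bw,lp_over_bw
2-4 Male,0.0030993,0.024071
2-4 Female,0.0033134,0.025328
18-30 Male,6.9089e-4,0.0084331
18-30 Female,0.0010057,0.0096996
60-70 Male,5.5139e-4,0.008323
60-70 Female,6.4089e-4,0.0093959
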