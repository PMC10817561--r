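wavelength_nm,tissue,mu_cm_inv,sd
780,meat,4.004,0.286
780,bone,4.758,0.405
780,skin,2.522,0.245
808,meat,3.335,0.274
808,bone,4.359,0.343
808,skin,2.454,0.249
980,meat,3.134,0.282
980,bone,3.619,0.315
980,skin,1.935,0.188
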