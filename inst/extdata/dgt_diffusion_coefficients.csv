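metal,temperature_c,diffusion_cm2_s
Ni,20,5.08e-6
Ni,25,5.77e-6
Cu,20,5.48e-6
Cu,25,6.23e-6
Cd,25,6.09e-6
Zn,25,6.08e-6
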