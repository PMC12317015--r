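architecture,minority_f1_before,minority_f1_after,improvement_printed,improvement_pct_printed
Dual-Gland GAN,0.777,0.896,0.119,15.3
ECP-IGANN,0.777,0.876,0.099,12.8
GSIP-GAN,0.777,0.864,0.087,11.2
MCI-GAN,0.777,0.851,0.074,9.5
WGAN,0.777,0.842,0.065,8.4
CycleGAN,0.777,0.836,0.059,7.6
Conditional GAN,0.777,0.834,0.057,7.3
DCGAN,0.777,0.827,0.050,6.4
Traditional GAN,0.777,0.812,0.035,4.5
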