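architecture,precision,recall,f1_printed
Dual-Gland GAN,0.872,0.835,0.853
Traditional GAN,0.631,0.458,0.531
DCGAN,0.712,0.582,0.641
WGAN,0.765,0.673,0.716
Pix2Pix GAN,0.823,0.764,0.792
Conditional GAN,0.791,0.712,0.749
CycleGAN,0.812,0.752,0.781
GSIP-GAN,0.841,0.798,0.819
ECP-IGANN,0.857,0.813,0.834
MCI-GAN,0.831,0.784,0.807
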