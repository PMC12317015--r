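architecture,quality,diversity,combined_printed,relative_improvement_printed
Dual-Gland GAN,0.912,0.894,0.903,NA
Traditional GAN,0.482,0.427,0.454,98.9
DCGAN,0.605,0.563,0.584,54.6
WGAN,0.683,0.647,0.665,35.8
Pix2Pix GAN,0.758,0.712,0.735,22.9
Conditional GAN,0.726,0.681,0.703,28.4
CycleGAN,0.751,0.705,0.728,24.0
GSIP-GAN,0.835,0.804,0.819,10.3
ECP-IGANN,0.862,0.827,0.844,7.0
MCI-GAN,0.821,0.793,0.807,11.9
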