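model,gap_before,gap_after,cross_before,cross_after,robustness_score_printed
ResNet-50,6.8,3.2,73.5,85.3,1.162
DenseNet-121,6.1,2.9,75.2,86.7,1.153
EfficientNet-B3,5.7,2.4,76.3,88.1,1.155
Vision Transformer,5.9,2.1,74.8,88.5,1.183
MobileNetV3,7.3,3.7,71.4,82.6,1.157
Inception-v4,6.4,2.8,74.1,85.9,1.159
Swin Transformer,5.4,2.0,76.9,89.3,1.161
ConvNeXt,5.8,2.5,75.6,87.4,1.156
RegNet-Y,6.9,3.3,72.8,84.1,1.155
NFNet,5.2,1.8,77.4,89.8,1.160
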