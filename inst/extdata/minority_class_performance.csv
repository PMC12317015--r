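model,minority_f1_before,minority_f1_after,balanced_acc_before,balanced_acc_after,improvement_ratio_printed
ResNet-50,0.762,0.881,0.812,0.904,1.156
DenseNet-121,0.781,0.892,0.828,0.915,1.142
EfficientNet-B3,0.790,0.907,0.837,0.928,1.148
Vision Transformer,0.778,0.913,0.825,0.932,1.173
MobileNetV3,0.741,0.858,0.794,0.885,1.158
Inception-v4,0.773,0.889,0.821,0.912,1.150
Swin Transformer,0.796,0.918,0.841,0.936,1.153
ConvNeXt,0.784,0.903,0.831,0.924,1.152
RegNet-Y,0.757,0.874,0.806,0.897,1.154
NFNet,0.803,0.925,0.846,0.941,1.152
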