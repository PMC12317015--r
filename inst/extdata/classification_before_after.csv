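model,accuracy_before,accuracy_after,f1_before,f1_after,auc_before,auc_after
ResNet-50,84.3,91.7,0.837,0.913,0.864,0.932
DenseNet-121,85.8,92.4,0.852,0.920,0.875,0.938
EfficientNet-B3,86.2,93.5,0.859,0.931,0.882,0.947
Vision Transformer,85.1,93.9,0.848,0.935,0.873,0.951
MobileNetV3,82.7,89.3,0.821,0.889,0.848,0.914
Inception-v4,84.9,92.1,0.843,0.917,0.867,0.935
Swin Transformer,86.4,94.2,0.861,0.939,0.885,0.953
ConvNeXt,85.7,93.1,0.853,0.927,0.876,0.942
RegNet-Y,83.9,90.8,0.835,0.904,0.859,0.925
NFNet,86.8,94.7,0.864,0.944,0.889,0.957
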