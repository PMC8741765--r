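model,accuracy,precision,sensitivity,specificity,f1,error_rate
PCA-GA-SVM,0.670,0.669,0.769,0.555,0.715,0.329
NonInvasive,0.763,0.691,0.728,0.607,0.774,0.317
GreedySnake,0.801,0.760,0.803,0.669,0.792,0.258
ResNet34,0.875,0.890,0.907,0.826,0.898,0.125
SqueezeNet,0.856,0.865,0.899,0.793,0.882,0.143
AlexNet,0.863,0.870,0.905,0.801,0.887,0.137
RandomForest,0.877,0.881,0.893,0.829,0.890,0.133
Stacking,0.892,0.894,0.912,0.850,0.917,0.119
GA-XGBT,0.906,0.911,0.899,0.872,0.934,0.103
SVM,0.927,0.932,0.945,0.917,0.955,0.085
ResNet50,0.929,0.961,0.956,0.776,0.958,0.071
ResNet50-RBFNN,0.944,0.968,0.965,0.819,0.967,0.056
ResNet50-DeepRBFNN,0.984,0.989,0.991,0.943,0.990,0.016
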