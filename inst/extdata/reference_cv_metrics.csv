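features,classifier,pca,accuracy_mean,accuracy_std,sensitivity_mean,sensitivity_std,specificity_mean,specificity_std,precision_mean,precision_std,f1_mean,f1_std,roc_auc_mean,roc_auc_std,balanced_accuracy_mean,balanced_accuracy_std,scaler
ADC,MLP,NA,77.00,5.540,91.86,1.560,59.73,12.174,73.07,5.448,81.26,3.493,77.86,4.091,75.80,5.994,L1 Normalizer
ADC,MLP,17,79.25,2.250,87.91,2.712,69.19,3.461,76.87,2.155,81.99,1.943,79.13,2.235,78.55,2.283,None
PZ,ADA,NA,78.23,1.462,83.24,2.111,71.61,2.180,79.50,1.286,81.31,1.341,77.66,1.448,77.43,1.452,Robust
PZ,RFC,6,78.00,1.341,85.41,1.576,68.21,1.557,78.03,1.022,81.54,1.172,77.29,1.331,76.81,1.335,None
CZ,DT,NA,73.82,3.493,92.30,2.706,35.83,8.094,74.79,2.573,82.60,2.214,70.21,2.950,64.07,4.509,Robust
CZ,MLP,4,70.64,3.016,82.57,4.207,46.11,3.557,75.88,1.509,79.05,2.508,66.93,2.827,64.34,2.699,Min Max
CZ+PZ,RFC,NA,84.08,1.144,93.24,1.351,71.96,1.964,81.48,1.071,86.96,0.930,83.30,1.134,82.60,1.192,Standardization
CZ+PZ,DT,8,77.54,2.403,84.59,2.847,68.21,3.977,77.91,2.256,81.08,2.020,76.88,2.401,76.40,2.490,None
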