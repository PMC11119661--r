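gene_id,0,0.071429,0.142857,0.214286,0.285714,0.357143,0.428571,0.5,0.571429,0.642857,0.714286,0.785714,0.857143,0.928571,1
g001,1.281755,0.981176,0.827038,0.617033,0.474279,0.385568,0.295116,0.230567,0.217389,0.129804,0.149853,0.090982,0.11578,0.096874,0.105571
g002,2.454803,2.289266,2.257703,2.204815,2.162854,2.121421,2.089907,2.102913,2.030527,2.01728,1.997015,2.007927,1.965415,1.931297,1.900075
g003,0.243877,0.053451,0.018781,1e-4,0.00459,0.017384,1e-4,1e-4,1e-4,1e-4,1e-4,0.003383,8.06e-4,0.00724,0.004433
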