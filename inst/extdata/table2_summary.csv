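instrument,total_H,ci_lower,ci_upper,alpha,n_obs
AS-18-D,0.513,0.41,0.63,0.89,57
PHQ9,0.510,0.42,0.61,0.88,59
MADRS,0.339,0.25,0.43,0.81,56
MADRS_reduced,0.415,0.31,0.51,0.84,56
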