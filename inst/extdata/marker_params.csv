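name,quant_mz,rt1_s,rt2_s,weight,sign,cutoff
benzene,78,171.30,1.2,1.33,-1,1.10
"2,3,4-trimethyl-pentane",71,245.67,1.2,1.45,-1,0.35
"1,4-dimethyl-trans-cyclohexane",97,280.02,1.3,1.26,-1,0.059
"2,2,4-trimethyl-hexane",57,285.02,1.2,1.37,-1,0.70
"1,7,7-trimethyl-tricyclo[2.2.1.0(2,6)]heptane",93,500.15,1.6,1.28,-1,0.045
4-ethyl-3-octene,69,578.11,1.5,1.27,-1,0.031
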