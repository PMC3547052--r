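taxon,temporal_natural_n,pterygoid_natural_n,temporal_scaled_n,pterygoid_scaled_n
O. tetraspis,1.37,1.27,11.37,10.54
C. moreletii,14.04,14.04,10.40,10.40
C. novaeguineae,4.37,4.38,11.71,11.72
C. intermedius,24.70,24.65,9.81,9.79
C. johnstoni,1.96,1.68,11.52,9.87
M. cataphractus,12.34,11.53,12.34,11.53
T. schlegelii,10.56,12.29,11.38,13.25
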