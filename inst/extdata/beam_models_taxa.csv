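taxon,abbrev,angle_deg,length_mm,symphysis_mm,width_mm
O. tetraspis,Ot,18.10,2.42,0.40,1.32
C. moreletii,Cm,19.32,2.32,0.36,1.37
C. novaeguineae,Cng,15.04,3.01,0.53,1.33
C. intermedius,Ci,15.42,3.20,0.71,1.38
C. johnstoni,Cj,12.78,3.69,0.83,1.30
M. cataphractus,Mc,16.19,3.18,0.80,1.38
T. schlegelii,Ts,22.15,3.68,1.94,1.42
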