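taxon,abbrev,angle_deg,length_mm,jaw_hinge_mm,symphysis_mm,width_mm
O. tetraspis,Ot,13.91,266.21,234.05,35.15,148.75
C. moreletii,Cm,13.75,273.49,229.43,35.72,158.30
C. novaeguineae,Cng,10.47,346.68,298.81,52.84,143.48
C. intermedius,Ci,10.07,363.58,314.93,66.60,151.23
C. johnstoni,Cj,9.71,411.38,364.25,80.09,147.05
M. cataphractus,Mc,11.72,369.40,309.88,77.70,152.26
T. schlegelii,Ts,18.37,413.61,362.93,191.96,160.90
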