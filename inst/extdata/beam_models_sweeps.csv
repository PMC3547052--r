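block,angle_deg,length_mm,symphysis_mm,width_mm
CL-CSL-VA-VW,10,4.0,1.5,0.4
CL-CSL-VA-VW,20,4.0,1.5,0.9
CL-CSL-VA-VW,30,4.0,1.5,1.3
CL-CSL-VA-VW,40,4.0,1.5,1.8
CL-CSL-VA-VW,50,4.0,1.5,2.3
CL-CW-VSL-VA,10,9.1,1.5,1.3
CL-CW-VSL-VA,20,9.1,5.3,1.3
CL-CW-VSL-VA,30,9.1,6.6,1.3
CL-CW-VSL-VA,40,9.1,7.2,1.3
CL-CW-VSL-VA,50,9.1,7.6,1.3
CA-CW-VSL-VL,44,3.0,0.5,2.0
CA-CW-VSL-VL,44,3.5,1.0,2.0
CA-CW-VSL-VL,44,4.0,1.5,2.0
CA-CW-VSL-VL,44,4.5,2.0,2.0
CA-CW-VSL-VL,44,5.0,2.5,2.0
CSL-CW-VL-VA,10,9.1,1.5,1.3
CSL-CW-VL-VA,20,5.3,1.5,1.3
CSL-CW-VL-VA,30,4.0,1.5,1.3
CSL-CW-VL-VA,40,3.3,1.5,1.3
CSL-CW-VL-VA,50,2.9,1.5,1.3
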