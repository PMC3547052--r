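analysis,response_model,rank,predictors,intercept,slope1,slope2,df,logLik,AICc,dAICc,akaike_weight
shake_beam,beam,1,ln(Symphyseal L.),-1.55,0.97,,3,32.12,-50.24,0.00,1.00
shake_beam,beam,2,ln(Length),-4.78,2.58,,3,-0.21,14.43,64.67,0.00
shake_beam,beam,3,ln(Angle),-3.67,0.62,,3,-5.01,24.02,74.26,0.00
twist_beam,beam,1,ln(Angle),-2.86,0.47,,3,21.57,-29.13,0.00,1.00
twist_beam,beam,2,ln(Length),-1.32,-0.18,,3,8.29,-2.58,26.55,0.00
twist_beam,beam,3,ln(Symphyseal L.),-1.52,0.02,,3,7.75,-1.51,27.63,0.00
bite_fem,fem,1,ln(Length),-16.87,1.84,,3,10.46,-6.93,0.00,1.00
bite_fem,fem,2,PC1+PC2,-6.4,-0.3,-0.17,4,9.65,8.7,15.63,0.00
bite_fem,fem,3,PC1,-6.4,-0.3,,3,2.43,9.14,16.06,0.00
shake_fem,fem,1,PC1,-7.07,-0.31,,3,3.14,7.71,0.00,0.51
shake_fem,fem,2,ln(Symphyseal L.),-9.28,0.53,,3,3.06,7.88,0.17,0.47
shake_fem,fem,3,ln(Length),-14.06,1.23,,3,-0.09,14.18,6.47,0.02
shake_fem,fem,4,ln(Angle),-8.88,0.72,,3,-1.19,16.38,8.66,0.01
shake_fem,fem,5,PC1+PC2,-7.07,-0.31,0.03,4,3.27,21.45,13.74,0.00
twist_fem,fem,1,ln(Symphyseal L.),-10.52,0.66,,3,5.52,2.96,0.00,0.57
twist_fem,fem,2,ln(Length),-19.25,2.02,,3,4.67,4.66,1.69,0.24
twist_fem,fem,3,PC1,-7.77,-0.37,,3,3.92,6.16,3.19,0.12
twist_fem,fem,4,PC1+PC2,-7.77,-0.37,-0.14,4,10.46,7.07,4.11,0.07
twist_fem,fem,5,ln(Angle),-8.28,0.2,,3,-2.94,19.88,16.92,0.00
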