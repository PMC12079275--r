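sample,c_s_nF,d_capacitive,l_s_H,d_inductive,z_mag_kohm,theta_deg,r_kohm,x_kohm,dcr_Mohm
actin,97.58,16.28,-0.2591,16.28,26.63,3.494,26.71,-1.631,1.289
mixture,131.0,5.561,-0.1906,5.583,6.797,-10.18,6.699,-1.207,1.363
proteinoid,13.25,15.76,-1.861,15.73,177.0,3.615,177.1,-11.10,1.199
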