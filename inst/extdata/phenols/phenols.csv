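compound,file,pka
"2,4-dinitrophenol",dinitrophenol_24_gen3d.sdf,4.09
4-nitrophenol,nitrophenol_4_gen3d.sdf,7.15
2-chlorophenol,chlorophenol_2_gen3d.sdf,8.56
3-chlorophenol,chlorophenol_3_gen3d.sdf,9.12
m-cresol,cresol_m_gen3d.sdf,10.10
o-cresol,cresol_o_gen3d.sdf,10.30
propofol,propofol_gen3d.sdf,11.10
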