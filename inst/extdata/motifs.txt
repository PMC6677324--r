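>Ebox_M1 bHLH
0.030 0.910 0.030 0.030 0.030 0.030 
0.910 0.030 0.910 0.030 0.030 0.030 
0.030 0.030 0.030 0.910 0.030 0.910 
0.030 0.030 0.030 0.030 0.910 0.030 
>Ebox_M2 bHLH
0.030 0.910 0.250 0.250 0.030 0.030 
0.910 0.030 0.250 0.250 0.030 0.030 
0.030 0.030 0.250 0.250 0.030 0.910 
0.030 0.030 0.250 0.250 0.910 0.030 
>Fox_M3 forkhead
0.030 0.455 0.030 0.030 0.455 0.045 
0.030 0.045 0.030 0.030 0.045 0.455 
0.030 0.455 0.030 0.030 0.045 0.045 
0.910 0.045 0.910 0.910 0.455 0.455 
>Hth_M4 HTH
0.030 0.455 0.910 0.030 0.455 0.455 
0.030 0.045 0.030 0.030 0.045 0.045 
0.030 0.045 0.030 0.030 0.045 0.455 
0.910 0.455 0.030 0.910 0.455 0.045 
>Mads_M5 MADS
0.045 0.045 0.455 0.455 0.045 0.045 
0.455 0.455 0.045 0.045 0.455 0.455 
0.455 0.455 0.045 0.045 0.455 0.455 
0.045 0.045 0.455 0.455 0.045 0.045 
>Bzip_M6 bZIP
0.910 0.030 0.045 0.910 0.030 0.250 
0.030 0.030 0.045 0.030 0.910 0.250 
0.030 0.030 0.455 0.030 0.030 0.250 
0.030 0.910 0.455 0.030 0.030 0.250 
>Homeo_M7 homeodomain
0.030 0.910 0.910 0.030 0.045 0.250 
0.030 0.030 0.030 0.030 0.045 0.250 
0.030 0.030 0.030 0.030 0.455 0.250 
0.910 0.030 0.030 0.910 0.455 0.250 
>Nr_M8 nuclear_receptor
0.455 0.030 0.045 0.030 0.030 0.250 
0.045 0.030 0.045 0.030 0.910 0.250 
0.455 0.910 0.455 0.030 0.030 0.250 
0.045 0.030 0.455 0.910 0.030 0.250 
>Zf_M9 zinc_finger
0.045 0.030 0.030 0.030 0.250 0.250 
0.455 0.030 0.030 0.030 0.250 0.250 
0.455 0.910 0.910 0.910 0.250 0.250 
0.045 0.030 0.030 0.030 0.250 0.250 
>Ets_M10 ETS
0.045 0.030 0.030 0.910 0.455 0.250 
0.455 0.030 0.030 0.030 0.045 0.250 
0.455 0.910 0.910 0.030 0.045 0.250 
0.045 0.030 0.030 0.030 0.455 0.250 
>Pou_M11 POU
0.910 0.030 0.045 0.030 0.910 0.250 
0.030 0.030 0.045 0.910 0.030 0.250 
0.030 0.030 0.455 0.030 0.030 0.250 
0.030 0.910 0.455 0.030 0.030 0.250 
>Gata_M12 GATA
0.455 0.030 0.910 0.030 0.910 0.250 
0.045 0.030 0.030 0.030 0.030 0.250 
0.045 0.910 0.030 0.030 0.030 0.250 
0.455 0.030 0.030 0.910 0.030 0.250 
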