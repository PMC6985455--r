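# synthetic example screen (three conditions, daily imaging)
plate,well,cell_line,drug,dose_uM,bio_rep,tech_rep,time_h,confluency_pct
P1,A01,RPE1,DMSO,0,1,1,0,5.0
P1,A01,RPE1,DMSO,0,1,1,24,12.1
P1,A01,RPE1,DMSO,0,1,1,48,27.4
P1,A01,RPE1,DMSO,0,1,1,72,52.9
P1,A02,RPE1,drugA,1,1,1,0,5.1
P1,A02,RPE1,drugA,1,1,1,24,9.8
P1,A02,RPE1,drugA,1,1,1,48,18.7
P1,A02,RPE1,drugA,1,1,1,72,33.5
P1,A03,Mad2cKD,DMSO,0,1,1,0,4.9
P1,A03,Mad2cKD,DMSO,0,1,1,24,10.2
P1,A03,Mad2cKD,DMSO,0,1,1,48,20.8
P1,A03,Mad2cKD,DMSO,0,1,1,72,38.6
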