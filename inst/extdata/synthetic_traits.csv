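trait,unit,genotype,replicate,value
spike_number,count,P1,1,10.9
spike_number,count,P1,2,10.6
spike_number,count,P1,3,10.9
spike_number,count,P2,1,9.3
spike_number,count,P2,2,9.0
spike_number,count,P2,3,9.3
spike_number,count,F1,1,15.3
spike_number,count,F1,2,15.0
spike_number,count,F1,3,15.3
plant_height,cm,P1,1,78.5
plant_height,cm,P1,2,78.0
plant_height,cm,P1,3,78.4
plant_height,cm,P2,1,112.2
plant_height,cm,P2,2,111.7
plant_height,cm,P2,3,112.1
plant_height,cm,F1,1,100.8
plant_height,cm,F1,2,100.3
plant_height,cm,F1,3,100.7
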