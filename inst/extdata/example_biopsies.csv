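patient_id,x,y,z,counts,enhancing
p1,10.0,-5.0,30.0,90;100;110,1
p1,22.5,14.0,33.0,45;52;38,0
p2,-8.1,3.3,26.4,130;122;141,1
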