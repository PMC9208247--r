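"label","component","slope","b1","b2","b3","b4"
"item1","salience",1.55,-1.3226,-0.1161,0.5613,1.8258
"item2","mood modification",1.77,-1.2429,-0.339,0.096,1.7627
"item3","conflict",2.85,0.2737,1.2702,1.7404,2.5649
"item4","tolerance",4.15,0.1157,0.9205,1.3373,1.9614
"item5","relapse",2.51,-0.1633,0.6135,1.2112,2.1673
"item6","withdrawal",1.93,-0.2073,0.7461,1.3005,2.6684
"item7","presenting problems",3.1,0.4419,1.1742,1.6097,2.4
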