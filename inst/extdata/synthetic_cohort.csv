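sample_id,group,C18:0,C18:1n-9,C20:3n-6,C20:4n-6,C22:4n-6,C22:5n-3,C20:5n-3,C22:6n-3,other
Control_001,Control,266945.3,614001.8,35510.2,256753.4,4743.4,15971.1,20440.2,44895.9,1500406.2
Control_002,Control,320797.0,758028.8,32606.7,121479.7,2503.1,16659.1,25944.9,119994.5,1745186.7
Control_003,Control,284951.7,623260.4,35540.4,106555.7,4979.9,12948.5,23436.2,106184.5,1808285.3
Control_004,Control,365444.5,913559.8,62742.9,308465.1,8272.7,14387.8,14796.9,84560.8,1846644.0
Atorvastatin_001,Atorvastatin,231512.5,691055.6,35976.2,220597.0,6960.3,12754.2,7339.3,47868.3,1869896.4
Atorvastatin_002,Atorvastatin,249022.7,791557.1,40901.5,245317.0,4484.3,9037.4,6374.5,45753.1,1858381.1
Rosuvastatin_001,Rosuvastatin,252714.4,686615.2,36057.1,135112.4,4624.3,9313.1,10219.7,47879.3,1516816.6
Rosuvastatin_002,Rosuvastatin,259055.2,1073759.6,38921.1,215510.7,7291.8,11879.3,13371.6,71210.0,1810676.2
NoStatin_001,NoStatin,166274.9,708012.7,28604.9,200682.0,4621.8,8188.0,12648.9,42806.8,1385123.0
NoStatin_002,NoStatin,179007.2,763468.8,40410.6,231352.3,7112.6,10894.0,20958.7,61197.8,1532108.8
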