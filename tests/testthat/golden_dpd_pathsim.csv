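"","D001","D002","D003","D004","D005","D006","D007","D008","D009","D010","D011","D012"
"D001",1,0.4,0.4,0.4,0.4,0.4,0,0,0,0,0,0
"D002",0.4,1,0,0.5,0,0,0,0,0.4,0,0,0
"D003",0.4,0,1,0.5,0,0,0,0,0,0,0,0
"D004",0.4,0.5,0.5,1,0,0,0,0,0.4,0,0,0
"D005",0.4,0,0,0,1,0.5,0.666666666666667,0.5,0,0,0,0
"D006",0.4,0,0,0,0.5,1,0,0,0,0,0,0
"D007",0,0,0,0,0.666666666666667,0,1,0.666666666666667,0,0,0,0
"D008",0,0,0,0,0.5,0,0.666666666666667,1,0,0,0,0
"D009",0,0.4,0,0.4,0,0,0,0,1,0.4,0.4,0.4
"D010",0,0,0,0,0,0,0,0,0.4,1,0,0.5
"D011",0,0,0,0,0,0,0,0,0.4,0,1,0
"D012",0,0,0,0,0,0,0,0,0.4,0.5,0,1
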