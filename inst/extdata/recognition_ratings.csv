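"group","level_index","signal_count","noise_count"
"alcohol",1,100,300
"alcohol",2,150,200
"alcohol",3,300,100
"alcohol",4,100,150
"alcohol",5,200,150
"alcohol",6,150,100
"placebo",1,50,350
"placebo",2,100,250
"placebo",3,350,150
"placebo",4,150,100
"placebo",5,250,100
"placebo",6,100,50
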