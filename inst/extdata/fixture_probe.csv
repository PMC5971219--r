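"kind","id","x","y","z","separation"
"source","S1",0,0,0,20
"source","S2",40,0,0,20
"source","S3",20,20,0,20
"source","S4",20,-20,0,20
"detector","D1",20,0,0,20
"detector","D2",0,20,0,20
"detector","D3",40,20,0,20
"detector","D4",-20,0,0,20
"channel","S1-D1",NA,NA,NA,20
"channel","S2-D1",NA,NA,NA,20
"channel","S3-D1",NA,NA,NA,20
"channel","S4-D1",NA,NA,NA,20
"channel","S1-D2",NA,NA,NA,20
"channel","S3-D2",NA,NA,NA,20
"channel","S2-D3",NA,NA,NA,20
"channel","S3-D3",NA,NA,NA,20
"channel","S1-D4",NA,NA,NA,20
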