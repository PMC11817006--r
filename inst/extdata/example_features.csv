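"subject_id","trv","ade_s","adi_s","trr","label"
"S001",1138198.174,0.9943,1.3393,19.2595,"copd"
"S002",509463.4614,0.9102,1.0214,32.3332,"copd"
"S003",1362126.4822,0.6018,1.7443,32.0871,"copd"
"S004",240989.1084,1.8615,1.4504,28.8471,"copd"
"S005",559571.2815,0.05,0.94,12.8833,"copd"
"S006",924949.0722,0.7249,0.05,7.3594,"copd"
"S007",0,1.6339,0.6446,14.2132,"copd"
"S008",407673.4839,1.0255,0.1854,29.8394,"copd"
"S009",554128.9716,0.9519,0.05,21.4608,"copd"
"S010",520388.2525,1.2586,0.6301,23.8898,"copd"
"S011",0,2.3619,1.3093,20.4935,"control"
"S012",0,1.6322,1.2024,10.9708,"control"
"S013",492051.4431,1.775,0.9394,22.9263,"control"
"S014",159487.9749,2.5141,0.5311,10.8054,"control"
"S015",0,2.1238,2.2582,23.8652,"control"
"S016",298713.8184,1.6884,0.05,18.562,"control"
"S017",609267.1903,2.5103,2.2323,14.6589,"control"
"S018",609261.4335,1.3887,0.3681,12.3776,"control"
"S019",661175.6928,1.1239,2.0185,5.9037,"control"
"S020",155072.4708,1.8839,0.1614,15.5359,"control"
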