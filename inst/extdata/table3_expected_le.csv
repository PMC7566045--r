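group,year,observed_le,expected_le,difference
Global,1990,67.2,65.1,2.1
Global,2000,67.2,67.2,0.0
Global,2010,70.6,69.6,1.0
Global,2019,73.5,71.7,1.8
Low SDI,1990,53.8,52.3,1.5
Low SDI,2000,55.4,54.5,0.9
Low SDI,2010,60.5,58.7,1.8
Low SDI,2019,65.6,63.1,2.5
Low-middle SDI,1990,59.7,59.4,0.3
Low-middle SDI,2000,62.4,63.4,-1.0
Low-middle SDI,2010,66.5,67.1,-0.6
Low-middle SDI,2019,69.7,69.7,0.0
Middle SDI,1990,67.0,66.7,0.3
Middle SDI,2000,69.5,69.4,0.1
Middle SDI,2010,72.1,71.2,0.9
Middle SDI,2019,74.7,72.6,2.1
High-middle SDI,1990,70.4,70.4,0.0
High-middle SDI,2000,71.6,72.1,-0.5
High-middle SDI,2010,75.0,73.9,1.1
High-middle SDI,2019,77.5,75.2,2.3
High SDI,1990,76.0,75.9,0.1
High SDI,2000,78.1,77.6,0.5
High SDI,2010,80.4,79.0,1.4
High SDI,2019,81.2,80.2,1.0
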