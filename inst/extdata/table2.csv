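instrument,item,H,H_reduced
AS-18-D,AS-18-D1,0.326,NA
AS-18-D,AS-18-D2,0.590,NA
AS-18-D,AS-18-D3,0.460,NA
AS-18-D,AS-18-D4,0.576,NA
AS-18-D,AS-18-D5,0.557,NA
AS-18-D,AS-18-D6,0.491,NA
AS-18-D,AS-18-D7,0.543,NA
AS-18-D,AS-18-D8,0.513,NA
AS-18-D,AS-18-D9,0.582,NA
PHQ9,PHQ9:1,0.584,NA
PHQ9,PHQ9:2,0.603,NA
PHQ9,PHQ9:3,0.481,NA
PHQ9,PHQ9:4,0.478,NA
PHQ9,PHQ9:5,0.385,NA
PHQ9,PHQ9:6,0.588,NA
PHQ9,PHQ9:7,0.567,NA
PHQ9,PHQ9:8,0.400,NA
PHQ9,PHQ9:9,0.468,NA
MADRS,MADRS1,0.469,0.514
MADRS,MADRS2,0.442,0.476
MADRS,MADRS3,0.419,0.449
MADRS,MADRS4,0.103,NA
MADRS,MADRS5,0.338,0.359
MADRS,MADRS6,0.358,0.370
MADRS,MADRS7,0.281,0.349
MADRS,MADRS8,0.388,0.456
MADRS,MADRS9,0.371,0.410
MADRS,MADRS10,0.257,0.332
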