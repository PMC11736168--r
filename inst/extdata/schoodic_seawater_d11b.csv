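site,collection_date,temperature_c,d11b_sw_permil
Schoodic,2016-05-13,7,39.73
Schoodic,2016-10-05,13,39.77
Schoodic,2017-07-06,9,39.77
Schoodic,2017-11-02,13,39.69
Schoodic,2017-11-30,9,39.69
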