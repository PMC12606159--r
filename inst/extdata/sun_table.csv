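date,sunrise_local,sunset_local,site
2022-06-01,05:49,19:09,SynthReef
2022-06-02,05:49,19:09,SynthReef
2022-06-03,05:49,19:10,SynthReef
2022-06-04,05:48,19:10,SynthReef
2022-06-05,05:48,19:11,SynthReef
2022-06-06,05:48,19:11,SynthReef
2022-06-07,05:48,19:11,SynthReef
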