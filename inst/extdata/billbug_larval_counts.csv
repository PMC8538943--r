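location,year,grass_type,species,n
Utah,2018,cool_season,S_parvulus,15
Utah,2018,cool_season,S_venatus,2
Utah,2018,cool_season,S_minimus,0
Indiana,2020,cool_season,S_parvulus,28
Indiana,2020,cool_season,S_venatus,5
Indiana,2020,cool_season,S_minimus,8
Indiana,2020,warm_season,S_parvulus,33
Indiana,2020,warm_season,S_venatus,3
Indiana,2020,warm_season,S_minimus,0
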