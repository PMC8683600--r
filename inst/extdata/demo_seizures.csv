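record_id,date,scales,meat,claws,other,item_count,route,seizure_country,mode,detection_method,suspects_arrested,prosecuted,source_db,co_seized
TR-001,2019-07-21,8300,,,,,"Nigeria|Vietnam",VNM,sea,routine inspection,0,,TRAFFIC,
WJC-001,2019-07-24,8268,,,,,"Nigeria|Vietnam",VNM,sea,routine inspection,0,,WJC,
TR-002,2016-03-02,0.5,,,,,"Nigeria|Kenya|China",KEN,air,sniffer dogs,1,,TRAFFIC,
TR-003,2018-11-10,2.5 t,,,,,"Cameroon|Nigeria",NGA,land,intelligence,2,1,TRAFFIC,ivory 120 kg
TR-004,2018-05-19,,,,,23,"Nigeria|China",NGA,air,intelligence,1,,TRAFFIC,
TR-005,2020-01-15,9500,,,,,NGA,NGA,warehouse,intelligence,3,,TRAFFIC,
TR-006,2017-09-30,600,,,,,"Cote d'Ivoire|Nigeria|Vietnam",VNM,unknown,,,,TRAFFIC,
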