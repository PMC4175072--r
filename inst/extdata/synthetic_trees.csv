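site_id,tree_id,species,inner_ring_year,pith_offset_yr,coring_height_offset_yr,status,dbh_cm
demo1,demo1_t001,PIPO,1963,23,4,live,10.9
demo1,demo1_t002,PIPO,1779,1,4,dead,10.3
demo1,demo1_t003,PSME,1728,2,9,live,37.3
demo1,demo1_t004,PICO,1724,2,8,dead,19.8
demo1,demo1_t005,PSME,1749,3,9,dead,20.7
demo1,demo1_t006,PIPO,1738,23,4,dead,18.3
demo1,demo1_t007,PIPO,1797,5,4,dead,11
demo1,demo1_t008,PIPO,1804,5,4,live,30
demo1,demo1_t009,PSME,1871,4,9,live,20.7
demo1,demo1_t010,PSME,1859,1,9,live,21.9
demo1,demo1_t011,POTR,1855,4,1,dead,21.5
demo1,demo1_t012,PSME,1883,6,9,live,21.6
demo1,demo1_t013,PIPO,1862,6,4,live,23.1
demo1,demo1_t014,PICO,1867,6,8,live,22.1
demo1,demo1_t015,PIFL,1907,1,9,live,18.1
demo1,demo1_t016,PIPO,1902,4,4,live,17.7
demo1,demo1_t017,PIPO,1899,1,4,live,16
demo1,demo1_t018,PICO,1933,5,8,live,15.2
demo1,demo1_t019,PIPO,1899,4,4,dead,15.1
demo1,demo1_t020,PIPO,1918,1,4,live,17.2
demo1,demo1_t021,PIPO,1902,3,4,live,16.3
demo1,demo1_t022,PSME,1902,0,9,live,16.2
demo1,demo1_t023,PSME,1909,6,9,live,16.3
demo1,demo1_t024,PIPO,1930,6,4,live,13.9
demo1,demo1_t025,PIPO,1904,5,4,live,16
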