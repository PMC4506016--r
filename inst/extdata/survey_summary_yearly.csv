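year,seasons,effort_km,cells_present,sightings,group_size
2006,4,3887,73,131,981
2007,4,3757,89,137,1184
2008,2,1849,42,70,747
2009,4,4009,94,152,1601
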