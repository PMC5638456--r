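target_field,source_concept,mode
general/title,datasetName,map
general/abstract,absent,map
general/party,recordedBy,map
general/data_center,institutionCode,note
time/start,eventDate,map
time/end,eventDate,map
time/geological,earliestEpochOrLowestSeries,note
time/resolution,absent,map
time/extent,absent,map
space/location/name,locality,map
space/location/country,country,map
space/location/continent,continent,map
space/bounding_box,absent,map
space/point,decimalLatitude + decimalLongitude,map
space/resolution,absent,map
space/extent,absent,map
sphere/layer,absent,map
biome/physiognomy,habitat,note
organism/name/scientific,scientificName,map
organism/taxonomy,kingdom + phylum + class + order + family + genus,map
process/process/name,absent,map
method/approach,absent,map
method/context,absent,map
method/manipulated_variable,absent,map
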