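target_field,source_concept,mode
general/title,dataset/title,map
general/abstract,dataset/abstract/para,map
general/party,dataset/creator + dataset/contact,map
general/data_center,absent,map
time/start,coverage/temporalCoverage/rangeOfDates/beginDate/calendarDate,map
time/end,coverage/temporalCoverage/rangeOfDates/endDate/calendarDate,map
time/geological,absent,map
time/resolution,absent,map
time/extent,absent,map
space/location/name,coverage/geographicCoverage/geographicDescription,map
space/location/country,absent,map
space/location/continent,absent,map
space/bounding_box,coverage/geographicCoverage/boundingCoordinates,map
space/point,absent,map
space/resolution,absent,map
space/extent,absent,map
sphere/layer,absent,map
biome/physiognomy,absent,map
organism/name/scientific,absent,map
organism/taxonomy,coverage/taxonomicCoverage/taxonomicClassification,map
process/process/name,absent,map
method/approach,absent,map
method/context,absent,map
method/manipulated_variable,methods/methodStep/description,note
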