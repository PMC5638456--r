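target_field,source_concept,mode
general/title,DataSet/Metadata/Description/Representation/Title,map
general/abstract,DataSet/Metadata/Description/Representation/Details,map
general/party,DataSet/Metadata/Owners/Owner/Person/FullName,map
general/data_center,absent,map
time/start,Unit/Gathering/DateTime/ISODateTimeBegin,map
time/end,Unit/Gathering/DateTime/ISODateTimeEnd,map
time/geological,Unit/Gathering/Stratigraphy,note
time/resolution,absent,map
time/extent,absent,map
space/location/name,Unit/Gathering/LocalityText,map
space/location/country,Unit/Gathering/Country/Name,map
space/location/continent,absent,map
space/bounding_box,absent,map
space/point,Unit/Gathering/SiteCoordinateSets/SiteCoordinates/CoordinatesLatLong,map
space/resolution,absent,map
space/extent,absent,map
sphere/layer,Unit/Gathering/Biotope,note
biome/physiognomy,Unit/Gathering/Biotope,note
organism/name/scientific,Unit/Identifications/Identification/Result/TaxonIdentified/ScientificName/FullScientificNameString,map
organism/taxonomy,Unit/Identifications/Identification/Result/TaxonIdentified/HigherTaxa,note
process/process/name,absent,map
method/approach,absent,map
method/context,absent,map
method/manipulated_variable,absent,map
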