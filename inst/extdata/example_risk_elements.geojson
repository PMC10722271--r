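{"type":"FeatureCollection","features":[{"type":"Feature","geometry":{"type":"Point","coordinates":[1250,900]},"properties":{"element_type":"village","intensity":10,"max_distance":1500,"decay":"linear","exponent":1}},{"type":"Feature","geometry":{"type":"Point","coordinates":[2600,2100]},"properties":{"element_type":"factory","intensity":8,"max_distance":1000,"decay":"linear","exponent":1}},{"type":"Feature","geometry":{"type":"LineString","coordinates":[[0,1500],[1600,1700],[3600,1400]]},"properties":{"element_type":"road","intensity":6,"max_distance":800,"decay":"linear","exponent":1}},{"type":"Feature","geometry":{"type":"Polygon","coordinates":[[[500,2600],[1100,2700],[1000,3200],[450,3100],[500,2600]]]},"properties":{"element_type":"artificial_forest","intensity":4,"max_distance":500,"decay":"linear","exponent":1}},{"type":"Feature","geometry":{"type":"Polygon","coordinates":[[[2900,500],[3500,600],[3400,1100],[2850,1000],[2900,500]]]},"properties":{"element_type":"economic_forest","intensity":5,"max_distance":600,"decay":"linear","exponent":1}}]}
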