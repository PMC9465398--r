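ecosystem,area_km2,censored
Boreal heath barrens,9.0,FALSE
Coastal oak-beech forest,2.8,FALSE
Coastal oak-heath forest,19.8,FALSE
Coastal oak-hickory forest,6.3,FALSE
Coastal oak-holly forest,1.3,FALSE
Coastal oak-laurel forest,1.3,FALSE
Dwarf pine plains,5.6,FALSE
Great Lakes dunes,2.9,FALSE
Hempstead Plains grassland,0,TRUE
Maritime beach,10.8,FALSE
Maritime beech forest,0.3,FALSE
Maritime dunes,9.3,FALSE
Maritime freshwater interdunal swales,1.3,FALSE
Maritime grassland,0.6,FALSE
Maritime heathland,1.7,FALSE
Maritime holly forest,0,TRUE
Maritime oak forest,3.5,FALSE
Maritime pitch pine dune woodland,3.1,FALSE
Maritime red cedar forest,0.3,FALSE
Maritime shrubland,4.1,FALSE
Pitch pine-heath barrens,16.4,FALSE
Pitch pine-oak forest,133.2,FALSE
Pitch pine-oak-heath woodland,50.1,FALSE
Pitch pine-scrub oak barrens,37.8,FALSE
Successional blueberry heath,11.2,FALSE
Successional maritime forest,2.4,FALSE
Successional northern sandplain grassland,17.2,FALSE
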