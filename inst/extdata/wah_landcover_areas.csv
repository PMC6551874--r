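class,available_km2,spring_use_km2,spring_mean_use_km2,spring_selection,spring_mean_selection,fall_use_km2,fall_mean_use_km2,fall_selection,fall_mean_selection
Dwarf Shrub,304000,34172,20801,1.00,1.00,35719,14808,0.89,0.89
Herbaceous (Mesic),276234,32774,19888,1.05,1.05,17377,6460,0.48,0.42
Tussock Tundra,126671,25711,14883,1.80,1.69,48779,20615,2.92,2.93
Spruce Forest,87892,2358,1863,0.24,0.32,5403,2582,0.47,0.51
Tall Shrub,21372,2940,2052,1.22,1.46,5173,2452,1.84,2.12
Freshwater or Saltwater,19411,1018,617,0.46,0.45,1228,701,0.48,0.68
Mixed Forest,18670,132,127,0.06,0.10,332,203,0.14,0.18
Lichen,11674,1072,681,0.81,0.85,1284,520,0.84,0.86
Deciduous Forest,11452,257,197,0.20,0.27,337,211,0.22,0.34
Sparse Vegetation,9462,556,278,0.52,0.42,698,354,0.56,0.68
Fire Scar,8354,380,296,0.40,0.55,1716,730,1.56,1.38
Bareground,3417,106,72,0.27,0.29,315,92,0.70,0.48
Ice-Snow,433,5,3,0.11,0.11,10,3,0.18,0.12
"Urban, Agriculture, Road",62,0,0,0.07,0.01,2,0,0.19,0.08
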