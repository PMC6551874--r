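season,year,predicted_area_km2,mean_lon_w,sd_lon,dev_ew,mean_lat,sd_lat,dev_ns
spring,2010,34327,159.39317,1.9,88.0 E,66.38077,1.0,75.0 S
spring,2011,37240,158.07553,2.3,234.9 E,66.67267,1.0,42.4 S
spring,2012,42357,159.25842,4.2,103.0 E,66.41471,1.2,71.2 S
spring,2013,21641,160.76047,1.5,64.5 W,66.38118,0.9,74.9 S
spring,2014,38725,160.43486,2.2,28.1 W,67.19233,1.2,15.5 N
spring,2015,38914,161.29370,2.2,123.9 W,66.93916,1.2,12.7 S
spring,2016,41583,161.50840,1.8,147.8 W,67.55609,1.5,56.1 N
spring,2017,47198,159.58935,2.7,66.1 E,67.74343,1.4,77.0 N
spring,pooled,61095,160.18242,2.6,,67.05322,1.3,
fall,2010,55941,158.39526,2.3,199.3 E,67.04180,1.1,13.0 N
fall,2011,74071,160.00940,3.9,75.4 E,67.13202,1.4,23.1 N
fall,2012,56131,160.22082,2.4,51.8 E,66.98286,1.6,6.4 N
fall,2013,56684,160.56695,2.8,13.2 E,66.59784,1.2,36.5 S
fall,2014,49026,161.57044,3.1,98.7 W,66.57247,1.2,39.3 S
fall,2015,45176,162.89438,2.6,246.3 W,66.48665,1.3,48.9 S
fall,2016,61165,161.02317,3.0,37.6 W,67.12672,1.4,22.5 N
fall,2017,66510,159.65528,3.7,114.9 E,67.92607,1.1,111.6 N
fall,pooled,118415,160.68562,3.2,,66.92524,1.4,
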