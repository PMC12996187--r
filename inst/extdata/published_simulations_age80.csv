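scenario,stage,sci_m,dg_cm,bas_m2ha,num_ha,vol_m3ha,c_total,c_root,c_stem,c_branch,c_leaf,c_non,c_comm
Base,0,12,12.1,11.2,964,71.2,30.5,8.3,19.0,2.4,0.8,3.6,15.4
Base,0,16,15.5,17.4,916,121.6,55.3,15.6,34.2,4.3,1.2,6.5,27.8
Base,0,20,17.4,23.2,973,174.5,83.1,24.0,51.1,6.4,1.6,9.7,41.5
MAI50,0,12,13.1,11.8,877,75.6,32.4,8.9,20.2,2.6,0.8,3.8,16.4
MAI50,0,16,16.5,18.2,848,127.6,58.2,16.4,36.0,4.5,1.2,6.8,29.2
MAI50,0,20,18.6,24.4,900,183.2,87.5,25.3,53.8,6.8,1.6,10.2,43.6
MAI50,1,12,14.7,12.9,759,82.7,35.7,9.7,22.2,2.8,0.9,4.2,18.0
MAI50,1,16,17.7,19.2,782,134.2,61.4,17.3,38.0,4.8,1.3,7.2,30.8
MAI50,1,20,19.0,24.8,874,186.6,89.2,25.8,54.9,6.9,1.7,10.4,44.5
MAI50,2,12,13.3,12.0,860,76.5,32.9,9.0,20.5,2.6,0.8,3.9,16.6
MAI50,2,16,17.1,18.7,814,131.0,59.8,16.9,37.0,4.7,1.3,7.0,30.0
MAI50,2,20,19.6,25.5,839,191.4,91.6,26.5,56.3,7.1,1.7,10.7,45.7
MAI50,3,12,9.7,9.4,1280,59.6,25.3,6.9,15.8,2.0,0.6,3.0,12.8
MAI50,3,16,13.2,15.3,1120,107.2,48.5,13.7,30.0,3.8,1.0,5.7,24.3
MAI50,3,20,16.2,21.9,1066,164.7,78.3,22.6,48.2,6.0,1.5,9.1,39.1
MAI60,0,12,12.1,11.2,964,71.2,30.5,8.3,19.0,2.4,0.8,3.6,15.4
MAI60,0,16,15.3,17.2,932,120.3,54.7,15.4,33.9,4.3,1.2,6.4,27.5
MAI60,0,20,17.2,23.0,989,172.7,82.3,23.8,50.6,6.4,1.5,9.6,41.0
MAI60,1,12,13.8,12.3,820,78.8,33.9,9.3,21.1,2.7,0.9,4.0,17.1
MAI60,1,16,16.6,18.3,845,127.9,58.4,16.5,36.1,4.6,1.2,6.8,29.3
MAI60,1,20,17.9,23.7,944,177.8,84.8,24.5,52.2,6.6,1.6,9.9,42.3
MAI60,2,12,12.5,11.4,928,72.9,31.2,8.5,19.5,2.5,0.8,3.7,15.8
MAI60,2,16,16.1,17.8,879,124.8,56.9,16.0,35.2,4.4,1.2,6.7,28.5
MAI60,2,20,18.5,24.3,907,182.4,87.1,25.2,53.6,6.7,1.6,10.1,43.4
MAI60,3,12,9.1,8.9,1382,56.8,24.0,6.5,15.0,1.9,0.6,2.8,12.2
MAI60,3,16,12.4,14.6,1210,102.1,46.1,13.0,28.5,3.6,1.0,5.4,23.2
MAI60,3,20,15.2,20.9,1151,157.0,74.4,21.5,45.8,5.7,1.4,8.7,37.1
MAI70,0,12,11.4,10.6,1044,67.8,28.9,7.9,18.0,2.3,0.7,3.4,14.6
MAI70,0,16,14.4,16.4,1009,114.5,51.9,14.6,32.2,4.0,1.1,6.1,26.1
MAI70,0,20,16.1,21.9,1071,164.3,78.1,22.5,48.0,6.0,1.5,9.1,39.0
MAI70,1,12,13.1,11.9,875,75.7,32.5,8.9,20.2,2.6,0.8,3.8,16.4
MAI70,1,16,15.7,17.5,902,122.8,55.9,15.8,34.6,4.4,1.2,6.5,28.1
MAI70,1,20,16.9,22.7,1008,170.7,81.2,23.5,50.0,6.3,1.5,9.5,40.5
MAI70,2,12,11.9,11.0,991,70.0,29.9,8.2,18.7,2.3,0.8,3.5,15.1
MAI70,2,16,15.2,17.1,938,119.8,54.5,15.4,33.7,4.2,1.2,6.4,27.3
MAI70,2,20,17.5,23.3,968,175.1,83.4,24.1,51.3,6.5,1.6,9.7,41.6
MAI70,3,12,8.6,8.6,1475,54.5,23.0,6.3,14.4,1.8,0.6,2.7,11.7
MAI70,3,16,11.8,14.0,1291,98.0,44.1,12.4,27.4,3.4,0.9,5.2,22.2
MAI70,3,20,14.4,20.1,1229,150.7,71.3,20.6,43.9,5.5,1.3,8.3,35.6
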