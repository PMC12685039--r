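"site_id","mat_C","map_mm","ndep","ph","soc","cn","bd","soil_temp","delta_t","wfps","delta_wfps_pct","n2o_control","n2o_warmed"
"SYN01",3.5,620,12,5.1,42,14,0.8,8,2,38,-18,0.9,0.67480598190702
"SYN02",5.2,710,9,4.6,58,17,0.7,9.5,1.5,45,-15,1.4,0.807992270195937
"SYN03",2.1,540,7,4.9,36,13,0.9,6.2,3,33,-12,0.6,0.529914097203656
"SYN04",7.8,860,15,5.6,61,15,0.6,11,2,52,-9,2.1,1.27790347608403
"SYN05",4.4,790,11,5.2,48,16,0.75,9.1,4,41,-6,1.1,1.30783207500071
"SYN06",6.1,900,13,4.4,52,18,0.85,10.4,2.5,47,-4,0.8,0.552144090076581
"SYN07",8.9,980,18,5.9,39,12,0.95,12.3,1,55,-2,1.6,1.76749122017604
"SYN08",4.5,811,13.2,5.3,55,15,0.7,9,2,40,0,1,0.867038990296311
"SYN09",9.6,1250,21,4.8,66,19,0.65,13.1,3.5,58,3,1.3,2.10303552987549
"SYN10",6.8,1420,16,5,47,14,0.8,10.8,2,50,6,0.7,0.727566938438135
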