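"label","metric","value","weight","route","dose_mg","n_doses","fed","window_start_h","window_end_h","day"
"iv_auc72","auc_last",682,1,"iv_bolus",2.97,1,FALSE,0,72,NA
"oral_fasting_cmax","cmax",86,1,"oral",20,1,FALSE,0,120,NA
"oral_fasting_tmax","tmax",6.2,0.5,"oral",20,1,FALSE,0,120,NA
"oral_fasting_auc120","auc_last",1231,1,"oral",20,1,FALSE,0,120,NA
"oral_fed_cmax","cmax",69,1,"oral",20,1,TRUE,0,120,NA
"oral_fed_tmax","tmax",6.8,0.5,"oral",20,1,TRUE,0,120,NA
"cmin_day1","cmin_day",8.4,1,"oral",20,10,FALSE,0,240,1
"cmin_day2","cmin_day",11.45,1,"oral",20,10,FALSE,0,240,2
"cmin_day3","cmin_day",12.2,1,"oral",20,10,FALSE,0,240,3
"cmin_day4","cmin_day",12.4,1,"oral",20,10,FALSE,0,240,4
"cmin_day5","cmin_day",12.48,1,"oral",20,10,FALSE,0,240,5
"cmin_day6","cmin_day",12.53,1,"oral",20,10,FALSE,0,240,6
"cmin_day7","cmin_day",12.57,1,"oral",20,10,FALSE,0,240,7
"cmin_day8","cmin_day",12.6,1,"oral",20,10,FALSE,0,240,8
"cmin_day9","cmin_day",12.63,1,"oral",20,10,FALSE,0,240,9
"cmin_day10","cmin_day",12.79,1,"oral",20,10,FALSE,0,240,10
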