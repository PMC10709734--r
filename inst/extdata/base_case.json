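{"cohort_size":10000,"start_age":50,"horizon_years":27,"discount_rate":0.05,"wtp":85700,"tils_split":{"m1":3333,"m2":6667},"tils_test_cost":3000,"patient":{"height_cm":158,"weight_kg":59},"prices":{"docetaxel":139.28,"epirubicin":79.15,"cyclophosphamide":23.98,"palonosetron":53.8,"aprepitant":450,"dexamethasone":0.58,"gcsf":58.98},"ae_cost":{"act":21175,"tc":9201},"admin_cost":{"act":3200,"tc":2400},"lab_cost":{"act":1002,"tc":1005.04},"recurrence_cost":70319.9,"recurrence_cost_mode":"once","followup_cost":[1846,2128,1564],"utilities":{"chemo":{"pfs":0.8,"pd":0.5,"death":0},"spared":{"pfs":0.94,"pd":0.73,"death":0}},"regimen_assignment":"cost_table","survival":{"m1_dfs":{"family":"log_normal","lambda":2.88,"gamma":0.061},"m1_os":{"family":"log_normal","lambda":3.24,"gamma":-0.12},"m2_dfs":{"family":"weibull","lambda":0.002,"gamma":1.04},"m2_os":{"family":"log_normal","lambda":5.92,"gamma":0.36},"m3_dfs":{"family":"exponential","lambda":0.034},"m3_os":{"family":"weibull","lambda":0.015,"gamma":1.16}},"life_table":{"age":[0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31,32,33,34,35,36,37,38,39,40,41,42,43,44,45,46,47,48,49,50,51,52,53,54,55,56,57,58,59,60,61,62,63,64,65,66,67,68,69,70,71,72,73,74,75,76,77,78,79,80,81,82,83,84,85,86,87,88,89,90,91,92,93,94,95,96,97,98,99,100,101,102,103,104,105,106,107,108,109,110],"qx":[0.000529859574809555,0.000532683302357451,0.000535772943284663,0.0005391535379905,0.000542852484680889,0.000546899761342035,0.000551328168606591,0.000556173595472997,0.000561475310030035,0.00056727627753661,0.000573623508427157,0.000580568439057072,0.000588167348263502,0.000596481813106675,0.00060557920747184,0.000615533247557587,0.000626424588650809,0.000638341478002458,0.000651380469067986,0.000665647202867214,0.000681257262756363,0.000698337109492075,0.000717025104108537,0.000737472626828439,0.000759845300993822,0.000784324331837838,0.000811107970828617,0.000840413117311756,0.000872477070262057,0.000907559444138117,0.000945944264123533,0.00098794225744292,0.00103389335897519,0.00108416945104983,0.00113917735913194,0.00119936212707261,0.00126521059775231,0.00133725532727524,0.00141607886340678,0.00150231842169879,0.00159667099572036,0.00169989894104872,0.00181283607615756,0.00193639434712078,0.0020715711071172,0.00221945706611126,0.00238124497080405,0.0025582390800174,0.0027518655061014,0.00296368349876053,0.00319539775387478,0.00344887183646581,0.0037261428139076,0.00402943720281312,0.00436118834071197,0.00472405530164399,0.00512094348308545,0.00555502700012911,0.00602977303147723,0.00654896827045037,0.00711674764273162,0.00773762546074186,0.00841652919215852,0.00915883602682355,0.0099704124317691,0.0108576568878567,0.0118275460030035,0.0128876841954659,0.0140463571353246,0.0153125891221522,0.0166962045606269,0.0182078936721322,0.0198592825474145,0.0216630076011315,0.0236327944311739,0.02578354101119,0.0281314050504633,0.0306938952373934,0.0334899659369029,0.0365401147331279,0.0398664819910487,0.0434929513478971,0.0474452497301651,0.0517510451170737,0.0564400398281335,0.0615440565921989,0.0670971140492804,0.0731354876356863,0.0796977509999311,0.0868247921850253,0.0945597977885981,0.102948197176313,0.112037557582601,0.121877419600641,0.132519061166745,0.144015176723959,0.156419456865972,0.1697860525003,0.184168906544201,0.199620935529569,0.216193043438961,0.23393295086758,0.252883824502811,0.273082695286334,0.294558658878867,0.317330859630979,0.341406269642932,0.36677728812528,0.393419203533278,0.421287582077521,0.450315671191167]}}
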