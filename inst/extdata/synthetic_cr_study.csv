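"animal_id","arm","dose_mg_per_kg","day","bw_g","intake_kcal","fm_g"
"r001","adlib",0,-15,,102.63,
"r001","adlib",0,-14,,107.31,
"r001","adlib",0,-13,,106.54,
"r001","adlib",0,-12,,114.08,
"r001","adlib",0,-3,698.4,,237.9
"r001","adlib",0,0,702.5,113.87,
"r001","adlib",0,1,702.8,114.49,
"r001","adlib",0,2,699.2,111.07,
"r001","adlib",0,3,699,108.17,
"r001","adlib",0,4,703.7,103.52,
"r001","adlib",0,5,696.4,103.95,
"r001","adlib",0,6,700.1,101.68,
"r001","adlib",0,7,701.6,110.78,
"r001","adlib",0,8,709.1,112.4,
"r001","adlib",0,9,693.6,110,
"r001","adlib",0,10,700.3,95.37,
"r001","adlib",0,11,699.6,108.08,
"r001","adlib",0,12,701.1,104.75,233.3
"r001","adlib",0,13,700.4,110.71,
"r001","adlib",0,14,707.1,101.95,
"r001","adlib",0,15,693.8,100.31,
"r001","adlib",0,16,691.6,113.79,
"r001","adlib",0,17,692.9,110.1,
"r001","adlib",0,18,691.1,113.35,
"r001","adlib",0,19,693.4,107.8,
"r001","adlib",0,20,689.5,110.46,
"r001","adlib",0,21,701.3,102.21,
"r001","adlib",0,22,694.8,108.21,244.2
"r001","adlib",0,23,700.9,111.74,
"r001","adlib",0,24,696.1,100.14,
"r001","adlib",0,25,703.2,108.24,
"r001","adlib",0,26,699.4,,
"r002","adlib",0,-15,,101.06,
"r002","adlib",0,-14,,104.77,
"r002","adlib",0,-13,,104.71,
"r002","adlib",0,-12,,109.64,
"r002","adlib",0,-3,637.8,,141.3
"r002","adlib",0,0,643.8,100.85,
"r002","adlib",0,1,634.1,114.85,
"r002","adlib",0,2,638,104.59,
"r002","adlib",0,3,633,111.07,
"r002","adlib",0,4,626.5,110.1,
"r002","adlib",0,5,634.9,110.63,
"r002","adlib",0,6,632.4,108.4,
"r002","adlib",0,7,639.2,116.19,
"r002","adlib",0,8,631.7,112.81,
"r002","adlib",0,9,629.4,105.3,
"r002","adlib",0,10,628.2,109.84,
"r002","adlib",0,11,640.5,104.44,
"r002","adlib",0,12,630.9,114.21,146.7
"r002","adlib",0,13,635,113.63,
"r002","adlib",0,14,632.7,102.33,
"r002","adlib",0,15,625.9,110.42,
"r002","adlib",0,16,644.8,114.75,
"r002","adlib",0,17,638.8,108.97,
"r002","adlib",0,18,634.9,108.65,
"r002","adlib",0,19,640.7,108.67,
"r002","adlib",0,20,634.9,113.41,
"r002","adlib",0,21,635.2,104.51,
"r002","adlib",0,22,629.8,107.5,156.4
"r002","adlib",0,23,635.2,106.72,
"r002","adlib",0,24,632.4,112.83,
"r002","adlib",0,25,636.6,112.2,
"r002","adlib",0,26,631.6,,
"r003","cr40",0,-15,,96.88,
"r003","cr40",0,-14,,87.54,
"r003","cr40",0,-13,,86.3,
"r003","cr40",0,-12,,92.47,
"r003","cr40",0,-3,581.5,,164.1
"r003","cr40",0,0,578.4,54.37,
"r003","cr40",0,1,578.1,54.37,
"r003","cr40",0,2,564.7,54.37,
"r003","cr40",0,3,562.6,54.37,
"r003","cr40",0,4,571,54.37,
"r003","cr40",0,5,562.5,54.37,
"r003","cr40",0,6,557.8,54.37,
"r003","cr40",0,7,558.9,54.37,
"r003","cr40",0,8,547,54.37,
"r003","cr40",0,9,546.9,54.37,
"r003","cr40",0,10,544.1,54.37,
"r003","cr40",0,11,529.6,54.37,
"r003","cr40",0,12,531.5,54.37,124.1
"r003","cr40",0,13,540.3,54.37,
"r003","cr40",0,14,531.2,54.37,
"r003","cr40",0,15,517.9,54.37,
"r003","cr40",0,16,503.7,54.37,
"r003","cr40",0,17,517,54.37,
"r003","cr40",0,18,510.8,54.37,
"r003","cr40",0,19,505.8,54.37,
"r003","cr40",0,20,507.9,54.37,
"r003","cr40",0,21,512.3,54.37,
"r003","cr40",0,22,500.8,54.37,131.6
"r003","cr40",0,23,498.1,54.37,
"r003","cr40",0,24,503.2,54.37,
"r003","cr40",0,25,490.9,54.37,
"r003","cr40",0,26,487.2,,
"r004","cr40",0,-15,,125.96,
"r004","cr40",0,-14,,126.92,
"r004","cr40",0,-13,,130.83,
"r004","cr40",0,-12,,131.28,
"r004","cr40",0,-3,777,,246.3
"r004","cr40",0,0,778.8,75.01,
"r004","cr40",0,1,766.8,75.01,
"r004","cr40",0,2,765.7,75.01,
"r004","cr40",0,3,757.2,75.01,
"r004","cr40",0,4,753.2,75.01,
"r004","cr40",0,5,740.5,75.01,
"r004","cr40",0,6,736.1,75.01,
"r004","cr40",0,7,736,75.01,
"r004","cr40",0,8,731.6,75.01,
"r004","cr40",0,9,719.4,75.01,
"r004","cr40",0,10,712.5,75.01,
"r004","cr40",0,11,713,75.01,
"r004","cr40",0,12,702.6,75.01,211.5
"r004","cr40",0,13,695.4,75.01,
"r004","cr40",0,14,698.5,75.01,
"r004","cr40",0,15,696.3,75.01,
"r004","cr40",0,16,692.8,75.01,
"r004","cr40",0,17,684.8,75.01,
"r004","cr40",0,18,683.7,75.01,
"r004","cr40",0,19,675.5,75.01,
"r004","cr40",0,20,680.4,75.01,
"r004","cr40",0,21,655.7,75.01,
"r004","cr40",0,22,660.8,75.01,195.4
"r004","cr40",0,23,659.2,75.01,
"r004","cr40",0,24,649.1,75.01,
"r004","cr40",0,25,650.3,75.01,
"r004","cr40",0,26,650.7,,
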