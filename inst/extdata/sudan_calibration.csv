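label,concentration,area
para_red,14.4,2916.6
para_red,21.6,4691.8
para_red,28.8,6107.6
para_red,36,7119.1
para_red,43.2,8108.6
para_red,57.6,10087.2
para_red,72,12301.7
sudan_i,20.4,4340.9
sudan_i,30.6,5189.6
sudan_i,40.8,7012.2
sudan_i,51,7959.4
sudan_i,61.2,8931.8
sudan_i,81.6,11877.7
sudan_i,102,14510
sudan_ii,50.2,8201
sudan_ii,75.3,10266
sudan_ii,100.4,12857
sudan_ii,125.5,14852.2
sudan_ii,150.6,18052.2
sudan_ii,200.8,21973.5
sudan_ii,251,27599.5
sudan_iii,49.4,7171.1
sudan_iii,74.1,11539.4
sudan_iii,98.8,16825.9
sudan_iii,123.5,18473.6
sudan_iii,148.2,24582.9
sudan_iii,197.6,30915.7
sudan_iii,247,39575.2
sudan_iv,121.2,7367.9
sudan_iv,181.8,12883.9
sudan_iv,242.4,16985.5
sudan_iv,303,20513.8
sudan_iv,363.6,23914.1
sudan_iv,484.8,29937.4
sudan_iv,606,38845.5
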