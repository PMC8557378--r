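level,tree,layer,method,n_ref,n_total,n_p,n_c,n_o,accuracy_pct,ec_pct,eo_pct
whorl,11,total,treeqsm,32,20,15,5,17,40.54,13.89,44.44
whorl,11,upper,treeqsm,9,0,0,0,9,0.00,0.00,100.00
whorl,11,middle,treeqsm,12,12,10,2,2,71.43,14.29,14.29
whorl,11,lower,treeqsm,11,8,5,3,6,35.71,21.43,42.86
whorl,11,total,tsm_tls,32,29,26,3,6,74.29,8.57,17.14
whorl,11,upper,tsm_tls,9,11,9,2,0,81.82,18.18,0.00
whorl,11,middle,tsm_tls,12,11,10,1,2,76.92,7.69,15.38
whorl,11,lower,tsm_tls,11,7,7,0,4,63.64,0.00,36.36
whorl,12,total,treeqsm,41,55,29,26,12,43.28,38.81,17.91
whorl,12,upper,treeqsm,13,5,5,0,8,38.46,0.00,61.54
whorl,12,middle,treeqsm,16,30,16,14,0,53.33,46.67,0.00
whorl,12,lower,treeqsm,12,20,8,12,4,33.33,50.00,16.67
whorl,12,total,tsm_tls,41,46,32,14,9,58.18,25.45,16.36
whorl,12,upper,tsm_tls,13,9,9,0,4,69.23,0.00,30.77
whorl,12,middle,tsm_tls,16,22,16,6,0,72.73,27.27,0.00
whorl,12,lower,tsm_tls,12,15,7,8,5,35.00,40.00,25.00
whorl,31,total,treeqsm,49,78,37,41,12,41.11,45.56,13.33
whorl,31,upper,treeqsm,23,16,12,4,11,44.44,14.81,40.74
whorl,31,middle,treeqsm,16,41,16,25,0,39.02,60.98,0.00
whorl,31,lower,treeqsm,10,21,9,12,1,40.91,54.55,4.55
whorl,31,total,tsm_tls,49,53,36,17,13,54.55,25.76,19.70
whorl,31,upper,tsm_tls,23,15,13,2,10,52.00,8.00,40.00
whorl,31,middle,tsm_tls,16,25,14,11,2,51.85,40.74,7.41
whorl,31,lower,tsm_tls,10,13,9,4,1,64.29,28.57,7.14
whorl,32,total,treeqsm,41,45,27,18,14,45.76,30.51,23.73
whorl,32,upper,treeqsm,18,5,4,1,14,21.05,5.26,73.68
whorl,32,middle,treeqsm,15,17,15,2,0,88.24,11.76,0.00
whorl,32,lower,treeqsm,8,23,8,15,0,34.78,65.22,0.00
whorl,32,total,tsm_tls,41,46,33,13,8,61.11,24.07,14.81
whorl,32,upper,tsm_tls,18,17,12,5,6,52.17,21.74,26.09
whorl,32,middle,tsm_tls,15,16,13,3,2,72.22,16.67,11.11
whorl,32,lower,tsm_tls,8,13,8,5,0,61.54,38.46,0.00
whorl,41,total,treeqsm,55,51,31,20,24,41.33,26.67,32.00
whorl,41,upper,treeqsm,29,14,9,5,20,26.47,14.71,58.82
whorl,41,middle,treeqsm,16,28,15,13,1,51.72,44.83,3.45
whorl,41,lower,treeqsm,10,9,7,2,3,58.33,16.67,25.00
whorl,41,total,tsm_tls,55,43,37,6,18,60.66,9.84,29.51
whorl,41,upper,tsm_tls,29,15,14,1,15,46.67,3.33,50.00
whorl,41,middle,tsm_tls,16,20,15,5,1,71.43,23.81,4.76
whorl,41,lower,tsm_tls,10,8,8,0,2,80.00,0.00,20.00
whorl,42,total,treeqsm,54,67,30,37,24,32.97,40.66,26.37
whorl,42,upper,treeqsm,31,14,10,4,21,28.57,11.43,60.00
whorl,42,middle,treeqsm,14,29,13,16,1,43.33,53.33,3.33
whorl,42,lower,treeqsm,9,24,7,17,2,26.92,65.38,7.69
whorl,42,total,tsm_tls,54,52,34,18,20,47.22,25.00,27.78
whorl,42,upper,tsm_tls,31,16,14,2,17,42.42,6.06,51.52
whorl,42,middle,tsm_tls,14,19,13,6,1,65.00,30.00,5.00
whorl,42,lower,tsm_tls,9,17,7,10,2,36.84,52.63,10.53
whorl,all,total,treeqsm,272,316,169,147,103,40.33,35.17,24.40
whorl,all,total,tsm_tls,272,269,198,71,74,57.73,20.70,21.57
branch,11,total,treeqsm,87,19,18,1,69,20.45,1.14,78.41
branch,11,upper,treeqsm,37,0,0,0,37,0.00,0.00,100.00
branch,11,middle,treeqsm,34,11,11,0,23,32.35,0.00,67.65
branch,11,lower,treeqsm,16,8,7,1,9,41.18,5.88,52.94
branch,11,total,tsm_tls,87,69,65,4,22,71.43,4.40,24.18
branch,11,upper,tsm_tls,37,28,28,0,9,75.68,0.00,24.32
branch,11,middle,tsm_tls,34,27,25,2,9,69.44,5.56,25.00
branch,11,lower,tsm_tls,16,14,12,2,4,66.67,11.11,22.22
branch,12,total,treeqsm,81,38,37,1,44,45.12,1.22,53.66
branch,12,upper,treeqsm,29,5,5,0,24,17.24,0.00,82.76
branch,12,middle,treeqsm,35,20,20,0,15,57.14,0.00,42.86
branch,12,lower,treeqsm,17,13,12,1,5,66.67,5.56,27.78
branch,12,total,tsm_tls,81,86,69,17,12,70.41,17.35,12.24
branch,12,upper,tsm_tls,29,28,24,4,5,72.73,12.12,15.15
branch,12,middle,tsm_tls,35,37,30,7,5,71.43,16.67,11.90
branch,12,lower,tsm_tls,17,21,15,6,2,65.22,26.09,8.70
branch,31,total,treeqsm,70,59,49,10,21,61.25,12.50,26.25
branch,31,upper,treeqsm,18,13,11,2,7,55.00,10.00,35.00
branch,31,middle,treeqsm,34,29,24,5,10,61.54,12.82,25.64
branch,31,lower,treeqsm,18,17,14,3,4,66.67,14.29,19.05
branch,31,total,tsm_tls,70,79,61,18,7,70.93,20.93,8.14
branch,31,upper,tsm_tls,18,24,18,6,0,75.00,25.00,0.00
branch,31,middle,tsm_tls,34,40,31,9,1,75.61,21.95,2.44
branch,31,lower,tsm_tls,18,15,12,3,6,57.14,14.29,28.57
branch,32,total,treeqsm,50,42,32,10,18,53.33,16.67,30.00
branch,32,upper,treeqsm,20,5,5,0,15,25.00,0.00,75.00
branch,32,middle,treeqsm,16,16,14,2,2,77.78,11.11,11.11
branch,32,lower,treeqsm,14,21,13,8,1,59.09,36.36,4.55
branch,32,total,tsm_tls,50,74,48,26,2,63.16,34.21,2.63
branch,32,upper,tsm_tls,20,26,18,8,2,64.29,28.57,7.14
branch,32,middle,tsm_tls,16,25,16,9,0,64.00,36.00,0.00
branch,32,lower,tsm_tls,14,23,14,9,0,60.87,39.13,0.00
branch,41,total,treeqsm,63,45,39,6,24,56.52,8.70,34.78
branch,41,upper,treeqsm,27,13,11,2,16,37.93,6.90,55.17
branch,41,middle,treeqsm,28,23,21,2,7,70.00,6.67,23.33
branch,41,lower,treeqsm,8,9,7,2,1,70.00,20.00,10.00
branch,41,total,tsm_tls,63,91,63,28,0,69.23,30.77,0.00
branch,41,upper,tsm_tls,27,41,27,14,0,65.85,34.15,0.00
branch,41,middle,tsm_tls,28,35,28,7,0,80.00,20.00,0.00
branch,41,lower,tsm_tls,8,15,8,7,0,53.33,46.67,0.00
branch,42,total,treeqsm,67,46,43,3,23,62.32,4.35,33.33
branch,42,upper,treeqsm,25,11,10,1,15,38.46,3.85,57.69
branch,42,middle,treeqsm,28,23,22,1,5,78.57,3.57,17.86
branch,42,lower,treeqsm,14,12,11,1,3,73.33,6.67,20.00
branch,42,total,tsm_tls,67,87,61,26,6,65.59,27.96,6.45
branch,42,upper,tsm_tls,25,39,24,15,1,60.00,37.50,2.50
branch,42,middle,tsm_tls,28,32,26,6,2,76.47,17.65,5.88
branch,42,lower,tsm_tls,14,16,11,5,3,57.89,26.32,15.79
branch,all,total,treeqsm,418,249,218,31,199,48.66,6.92,44.42
branch,all,total,tsm_tls,418,486,367,119,49,68.60,22.24,9.16
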