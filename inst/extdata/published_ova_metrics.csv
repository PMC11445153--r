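class,model,auc_roc,accuracy,f1,sensitivity,specificity,precision,u_acc,u_f1,u_prec,u_sens,u_spec,u_auc_roc,brier
0,DNN,96.5,92.8,90.0,90.4,94.2,89.7,NA,NA,NA,NA,NA,NA,NA
1,DNN,97.3,93.4,90.6,91.7,94.3,89.6,NA,NA,NA,NA,NA,NA,NA
2,DNN,93.6,91.7,85.4,83.5,95.1,89.9,NA,NA,NA,NA,NA,NA,NA
0,MC Dropout,NA,NA,NA,NA,NA,NA,81.0,75.5,70.3,81.5,80.7,87.9,0.168
0,EBNN,NA,NA,NA,NA,NA,NA,92.6,90.0,86.9,93.3,92.1,95.0,0.157
0,EMC Dropout,NA,NA,NA,NA,NA,NA,87.5,80.7,90.7,72.6,95.9,95.1,0.178
1,MC Dropout,NA,NA,NA,NA,NA,NA,74.7,53.1,76.0,59.9,93.0,80.0,0.189
1,EBNN,NA,NA,NA,NA,NA,NA,70.7,73.7,82.4,71.4,97.5,93.4,0.182
1,EMC Dropout,NA,NA,NA,NA,NA,NA,83.5,72.3,88.0,61.7,95.5,95.8,0.165
2,MC Dropout,NA,NA,NA,NA,NA,NA,74.4,53.9,56.5,51.6,83.7,75.8,0.196
2,EBNN,NA,NA,NA,NA,NA,NA,87.8,75.5,87.5,65.1,97.0,90.6,0.185
2,EMC Dropout,NA,NA,NA,NA,NA,NA,71.8,65.0,77.2,62.8,91.0,84.4,0.190
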