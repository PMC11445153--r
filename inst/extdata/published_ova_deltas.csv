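class,model,metric,value,consistent
0,MC Dropout,u_acc,11.8,TRUE
0,MC Dropout,u_auc_roc,8.6,TRUE
0,MC Dropout,u_prec,19.4,TRUE
0,MC Dropout,u_sens,8.9,TRUE
0,EBNN,u_acc,0.2,TRUE
0,EBNN,u_auc_roc,1.5,TRUE
0,EBNN,u_prec,2.8,TRUE
0,EBNN,u_sens,2.9,TRUE
0,EMC Dropout,u_acc,5.3,TRUE
0,EMC Dropout,u_auc_roc,1.4,TRUE
0,EMC Dropout,u_prec,1.0,TRUE
0,EMC Dropout,u_sens,17.8,TRUE
1,MC Dropout,u_acc,18.7,TRUE
1,MC Dropout,u_auc_roc,17.3,TRUE
1,MC Dropout,u_prec,13.6,TRUE
1,MC Dropout,u_sens,31.8,TRUE
1,EBNN,u_acc,22.7,TRUE
1,EBNN,u_auc_roc,3.9,TRUE
1,EBNN,u_prec,7.2,TRUE
1,EBNN,u_sens,20.3,TRUE
1,EMC Dropout,u_acc,9.9,TRUE
1,EMC Dropout,u_auc_roc,1.5,TRUE
1,EMC Dropout,u_prec,1.6,TRUE
1,EMC Dropout,u_sens,30.0,TRUE
2,MC Dropout,u_acc,17.3,TRUE
2,MC Dropout,u_auc_roc,17.8,TRUE
2,MC Dropout,u_prec,31.0,FALSE
2,MC Dropout,u_sens,31.9,TRUE
2,EBNN,u_acc,3.9,TRUE
2,EBNN,u_auc_roc,3.0,TRUE
2,EBNN,u_prec,2.4,TRUE
2,EBNN,u_sens,18.4,TRUE
2,EMC Dropout,u_acc,19.9,TRUE
2,EMC Dropout,u_auc_roc,9.2,TRUE
2,EMC Dropout,u_prec,12.7,TRUE
2,EMC Dropout,u_sens,20.7,TRUE
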