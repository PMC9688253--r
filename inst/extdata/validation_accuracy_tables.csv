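classifier,dataset,strategy,dim_fused,acc_fused,dim_ranked,acc_ranked
DT,HAM 10000,CFS,2560,0.9110,2560,0.9110
DT,HAM 10000,AWFS,2560,0.9124,512+1024,0.9410
DT,HAM 10000,MOWFS-GA,2560,0.9116,512,0.9411
DT,HAM 10000,MOWFS-PSO,2560,0.9215,512,0.9412
DT,HAM 10000,MOWFS-AJS,2560,0.9219,1024,0.9401
DT,HAM 10000,FOWFS-GA,2560,0.9310,1015,0.9312
DT,HAM 10000,FOWFS-PSO,2560,0.9322,954,0.9412
DT,HAM 10000,FOWFS-AJS,2560,0.9322,914,0.9422
DT,BCN 20000,CFS,2560,0.8847,2560,0.8847
DT,BCN 20000,AWFS,2560,0.8925,512,0.9610
DT,BCN 20000,MOWFS-GA,2560,0.8948,512+1024,0.9611
DT,BCN 20000,MOWFS-PSO,2560,0.9012,512+1024+1024,0.9612
DT,BCN 20000,MOWFS-AJS,2560,0.8999,1121,0.9602
DT,BCN 20000,FOWFS-GA,2560,0.9015,998,0.9512
DT,BCN 20000,FOWFS-PSO,2560,0.9128,1019,0.9611
DT,BCN 20000,FOWFS-AJS,2560,0.9198,925,0.9622
NB,HAM 10000,CFS,2560,0.9118,2560,0.9118
NB,HAM 10000,AWFS,2560,0.9211,512,0.9411
NB,HAM 10000,MOWFS-GA,2560,0.9124,512,0.9421
NB,HAM 10000,MOWFS-PSO,2560,0.9158,1024,0.9422
NB,HAM 10000,MOWFS-AJS,2560,0.9199,1024+1024,0.9428
NB,HAM 10000,FOWFS-GA,2560,0.9210,995,0.9391
NB,HAM 10000,FOWFS-PSO,2560,0.9214,961,0.9438
NB,HAM 10000,FOWFS-AJS,2560,0.9218,1015,0.9448
NB,BCN 20000,CFS,2560,0.9001,2560,0.9001
NB,BCN 20000,AWFS,2560,0.9191,512+1024,0.9611
NB,BCN 20000,MOWFS-GA,2560,0.9125,1024,0.9621
NB,BCN 20000,MOWFS-PSO,2560,0.9215,512+1024,0.9622
NB,BCN 20000,MOWFS-AJS,2560,0.9244,512+1024+1024,0.9628
NB,BCN 20000,FOWFS-GA,2560,0.9248,1115,0.9594
NB,BCN 20000,FOWFS-PSO,2560,0.9314,1245,0.9632
NB,BCN 20000,FOWFS-AJS,2560,0.9325,998,0.9648
MLP,HAM 10000,CFS,2560,0.9211,2560,0.9211
MLP,HAM 10000,AWFS,2560,0.9214,1024,0.9550
MLP,HAM 10000,MOWFS-GA,2560,0.9244,512+1024,0.9552
MLP,HAM 10000,MOWFS-PSO,2560,0.9214,512+1024,0.9558
MLP,HAM 10000,MOWFS-AJS,2560,0.9254,512,0.9561
MLP,HAM 10000,FOWFS-GA,2560,0.9311,915,0.9342
MLP,HAM 10000,FOWFS-PSO,2560,0.9324,898,0.9537
MLP,HAM 10000,FOWFS-AJS,2560,0.9345,975,0.9562
MLP,BCN 20000,CFS,2560,0.9112,2560,0.9112
MLP,BCN 20000,AWFS,2560,0.9119,512+1024,0.9650
MLP,BCN 20000,MOWFS-GA,2560,0.9132,1024+1024,0.9652
MLP,BCN 20000,MOWFS-PSO,2560,0.9124,512,0.9658
MLP,BCN 20000,MOWFS-AJS,2560,0.9312,512+1024,0.9661
MLP,BCN 20000,FOWFS-GA,2560,0.9365,1124,0.9549
MLP,BCN 20000,FOWFS-PSO,2560,0.9378,954,0.9649
MLP,BCN 20000,FOWFS-AJS,2560,0.9411,929,0.9669
SVM,HAM 10000,CFS,2560,0.9225,2560,0.9225
SVM,HAM 10000,AWFS,2560,0.9315,1024+1024,0.9599
SVM,HAM 10000,MOWFS-GA,2560,0.9311,512,0.9611
SVM,HAM 10000,MOWFS-PSO,2560,0.9347,512+1024,0.9712
SVM,HAM 10000,MOWFS-AJS,2560,0.9348,512+1024,0.9612
SVM,HAM 10000,FOWFS-GA,2560,0.9378,1125,0.9479
SVM,HAM 10000,FOWFS-PSO,2560,0.9399,897,0.9679
SVM,HAM 10000,FOWFS-AJS,2560,0.9425,867,0.9779
SVM,BCN 20000,CFS,2560,0.9147,2560,0.9147
SVM,BCN 20000,AWFS,2560,0.9110,1024,0.9599
SVM,BCN 20000,MOWFS-GA,2560,0.9118,1024+512,0.9611
SVM,BCN 20000,MOWFS-PSO,2560,0.9210,1024+1024,0.9712
SVM,BCN 20000,MOWFS-AJS,2560,0.9211,512,0.9612
SVM,BCN 20000,FOWFS-GA,2560,0.9212,1005,0.9579
SVM,BCN 20000,FOWFS-PSO,2560,0.9245,905,0.9688
SVM,BCN 20000,FOWFS-AJS,2560,0.9311,899,0.9779
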