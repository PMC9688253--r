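dataset,classifier,method,accuracy
HAM 10000,DT,VGG16,0.9302
HAM 10000,DT,EfficientNetB0,0.9321
HAM 10000,DT,ResNet50,0.9315
HAM 10000,DT,CFS,0.9412
HAM 10000,DT,AWFS,0.9410
HAM 10000,DT,MOWFS-GA,0.9411
HAM 10000,DT,MOWFS-PSO,0.9412
HAM 10000,DT,MOWFS-AJS,0.9424
HAM 10000,DT,FOWFS-GA,0.9312
HAM 10000,DT,FOWFS-PSO,0.9412
HAM 10000,DT,FOWFS-AJS,0.9422
HAM 10000,NB,VGG16,0.9308
HAM 10000,NB,EfficientNetB0,0.9302
HAM 10000,NB,ResNet50,0.9311
HAM 10000,NB,CFS,0.9332
HAM 10000,NB,AWFS,0.9411
HAM 10000,NB,MOWFS-GA,0.9421
HAM 10000,NB,MOWFS-PSO,0.9422
HAM 10000,NB,MOWFS-AJS,0.9428
HAM 10000,NB,FOWFS-GA,0.9398
HAM 10000,NB,FOWFS-PSO,0.9438
HAM 10000,NB,FOWFS-AJS,0.9448
HAM 10000,MLP,VGG16,0.9302
HAM 10000,MLP,EfficientNetB0,0.9300
HAM 10000,MLP,ResNet50,0.9342
HAM 10000,MLP,CFS,0.9369
HAM 10000,MLP,AWFS,0.9550
HAM 10000,MLP,MOWFS-GA,0.9552
HAM 10000,MLP,MOWFS-PSO,0.9558
HAM 10000,MLP,MOWFS-AJS,0.9561
HAM 10000,MLP,FOWFS-GA,0.9349
HAM 10000,MLP,FOWFS-PSO,0.9549
HAM 10000,MLP,FOWFS-AJS,0.9569
HAM 10000,SVM,VGG16,0.9412
HAM 10000,SVM,EfficientNetB0,0.9341
HAM 10000,SVM,ResNet50,0.9416
HAM 10000,SVM,CFS,0.9477
HAM 10000,SVM,AWFS,0.9599
HAM 10000,SVM,MOWFS-GA,0.9611
HAM 10000,SVM,MOWFS-PSO,0.9712
HAM 10000,SVM,MOWFS-AJS,0.9612
HAM 10000,SVM,FOWFS-GA,0.9479
HAM 10000,SVM,FOWFS-PSO,0.9679
HAM 10000,SVM,FOWFS-AJS,0.9779
BCN 20000,DT,VGG16,0.9402
BCN 20000,DT,EfficientNetB0,0.9461
BCN 20000,DT,ResNet50,0.9415
BCN 20000,DT,CFS,0.9512
BCN 20000,DT,AWFS,0.9610
BCN 20000,DT,MOWFS-GA,0.9611
BCN 20000,DT,MOWFS-PSO,0.9612
BCN 20000,DT,MOWFS-AJS,0.9624
BCN 20000,DT,FOWFS-GA,0.9512
BCN 20000,DT,FOWFS-PSO,0.9612
BCN 20000,DT,FOWFS-AJS,0.9622
BCN 20000,NB,VGG16,0.9421
BCN 20000,NB,EfficientNetB0,0.9402
BCN 20000,NB,ResNet50,0.9451
BCN 20000,NB,CFS,0.9532
BCN 20000,NB,AWFS,0.9611
BCN 20000,NB,MOWFS-GA,0.9621
BCN 20000,NB,MOWFS-PSO,0.9622
BCN 20000,NB,MOWFS-AJS,0.9628
BCN 20000,NB,FOWFS-GA,0.9598
BCN 20000,NB,FOWFS-PSO,0.9638
BCN 20000,NB,FOWFS-AJS,0.9648
BCN 20000,MLP,VGG16,0.9502
BCN 20000,MLP,EfficientNetB0,0.9538
BCN 20000,MLP,ResNet50,0.9542
BCN 20000,MLP,CFS,0.9569
BCN 20000,MLP,AWFS,0.9650
BCN 20000,MLP,MOWFS-GA,0.9652
BCN 20000,MLP,MOWFS-PSO,0.9658
BCN 20000,MLP,MOWFS-AJS,0.9661
BCN 20000,MLP,FOWFS-GA,0.9549
BCN 20000,MLP,FOWFS-PSO,0.9649
BCN 20000,MLP,FOWFS-AJS,0.9669
BCN 20000,SVM,VGG16,0.9522
BCN 20000,SVM,EfficientNetB0,0.9541
BCN 20000,SVM,ResNet50,0.9546
BCN 20000,SVM,CFS,0.9572
BCN 20000,SVM,AWFS,0.9599
BCN 20000,SVM,MOWFS-GA,0.9611
BCN 20000,SVM,MOWFS-PSO,0.9712
BCN 20000,SVM,MOWFS-AJS,0.9612
BCN 20000,SVM,FOWFS-GA,0.9579
BCN 20000,SVM,FOWFS-PSO,0.9679
BCN 20000,SVM,FOWFS-AJS,0.9779
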