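"name","class","formula","mass"
"PC(32:1)","PC","C40H78NO8P",731.546505
"PC(32:2)","PC","C40H76NO8P",729.530855
"PC(32:4)","PC","C40H72NO8P",725.499555
"PC(34:1)","PC","C42H82NO8P",759.577805
"PC(34:2)","PC","C42H80NO8P",757.562155
"PC(34:4)","PC","C42H76NO8P",753.530855
"PC(36:1)","PC","C44H86NO8P",787.609105
"PC(36:2)","PC","C44H84NO8P",785.593455
"PC(36:4)","PC","C44H80NO8P",781.562155
"PC(38:1)","PC","C46H90NO8P",815.640405
"PC(38:2)","PC","C46H88NO8P",813.624755
"PC(38:4)","PC","C46H84NO8P",809.593455
"PC(40:1)","PC","C48H94NO8P",843.671705
"PC(40:2)","PC","C48H92NO8P",841.656055
"PC(40:4)","PC","C48H88NO8P",837.624755
"PE(32:1)","PE","C37H72NO8P",689.499555
"PE(32:2)","PE","C37H70NO8P",687.483905
"PE(32:4)","PE","C37H66NO8P",683.452605
"PE(34:1)","PE","C39H76NO8P",717.530855
"PE(34:2)","PE","C39H74NO8P",715.515205
"PE(34:4)","PE","C39H70NO8P",711.483905
"PE(36:1)","PE","C41H80NO8P",745.562155
"PE(36:2)","PE","C41H78NO8P",743.546505
"PE(36:4)","PE","C41H74NO8P",739.515205
"PE(38:1)","PE","C43H84NO8P",773.593455
"PE(38:2)","PE","C43H82NO8P",771.577805
"PE(38:4)","PE","C43H78NO8P",767.546505
"PE(40:1)","PE","C45H88NO8P",801.624755
"PE(40:2)","PE","C45H86NO8P",799.609105
"PE(40:4)","PE","C45H82NO8P",795.577805
"PS(32:1)","PS","C38H72NO10P",733.489384
"PS(32:2)","PS","C38H70NO10P",731.473734
"PS(32:4)","PS","C38H66NO10P",727.442434
"PS(34:1)","PS","C40H76NO10P",761.520684
"PS(34:2)","PS","C40H74NO10P",759.505034
"PS(34:4)","PS","C40H70NO10P",755.473734
"PS(36:1)","PS","C42H80NO10P",789.551984
"PS(36:2)","PS","C42H78NO10P",787.536334
"PS(36:4)","PS","C42H74NO10P",783.505034
"PS(38:1)","PS","C44H84NO10P",817.583284
"PS(38:2)","PS","C44H82NO10P",815.567634
"PS(38:4)","PS","C44H78NO10P",811.536334
"PS(40:1)","PS","C46H88NO10P",845.614585
"PS(40:2)","PS","C46H86NO10P",843.598934
"PS(40:4)","PS","C46H82NO10P",839.567634
"PA(32:1)","PA","C35H67O8P",646.457356
"PA(32:2)","PA","C35H65O8P",644.441706
"PA(32:4)","PA","C35H61O8P",640.410405
"PA(34:1)","PA","C37H71O8P",674.488656
"PA(34:2)","PA","C37H69O8P",672.473006
"PA(34:4)","PA","C37H65O8P",668.441706
"PA(36:1)","PA","C39H75O8P",702.519956
"PA(36:2)","PA","C39H73O8P",700.504306
"PA(36:4)","PA","C39H69O8P",696.473006
"PA(38:1)","PA","C41H79O8P",730.551256
"PA(38:2)","PA","C41H77O8P",728.535606
"PA(38:4)","PA","C41H73O8P",724.504306
"PA(40:1)","PA","C43H83O8P",758.582556
"PA(40:2)","PA","C43H81O8P",756.566906
"PA(40:4)","PA","C43H77O8P",752.535606
"PI(32:1)","PI","C41H77O13P",808.510179
"PI(32:2)","PI","C41H75O13P",806.494529
"PI(32:4)","PI","C41H71O13P",802.463229
"PI(34:1)","PI","C43H81O13P",836.541479
"PI(34:2)","PI","C43H79O13P",834.525829
"PI(34:4)","PI","C43H75O13P",830.494529
"PI(36:1)","PI","C45H85O13P",864.572779
"PI(36:2)","PI","C45H83O13P",862.557129
"PI(36:4)","PI","C45H79O13P",858.525829
"PI(38:1)","PI","C47H89O13P",892.604079
"PI(38:2)","PI","C47H87O13P",890.588429
"PI(38:4)","PI","C47H83O13P",886.557129
"PI(40:1)","PI","C49H93O13P",920.63538
"PI(40:2)","PI","C49H91O13P",918.61973
"PI(40:4)","PI","C49H87O13P",914.588429
"PC(O-34:1)","PC","C42H84NO7P",745.598541
"PC(O-36:4)","PC","C44H82NO7P",767.58289
"PC(O-38:5)","PC","C46H84NO7P",793.598541
"PC(O-40:5)","PC","C48H88NO7P",821.629841
"PC(O-40:6)","PC","C48H86NO7P",819.614191
"PE(O-36:2)","PE","C41H80NO7P",729.56724
"PE(O-38:4)","PE","C43H80NO7P",753.56724
"PE(O-40:6)","PE","C45H80NO7P",777.56724
"PA(O-40:6)","PA","C43H75O7P",734.525041
"PI(O-38:4)","PI","C47H85O12P",872.577865
"LPC(16:0)","LPC","C24H50NO7P",495.332489
"LPC(18:0)","LPC","C26H54NO7P",523.36379
"LPC(18:1)","LPC","C26H52NO7P",521.34814
"LPC(20:4)","LPC","C28H50NO7P",543.332489
"LPE(16:0)","LPE","C21H44NO7P",453.285539
"LPE(18:0)","LPE","C23H48NO7P",481.316839
"LPE(18:1)","LPE","C23H46NO7P",479.301189
"LPA(16:0)","LPA","C19H39O7P",410.24334
"LPA(18:0)","LPA","C21H43O7P",438.27464
"LPA(18:1)","LPA","C21H41O7P",436.25899
"LPS(18:0)","LPS","C24H48NO9P",525.306669
"LPS(18:1)","LPS","C24H46NO9P",523.291019
"LPI(18:0)","LPI","C27H53O12P",600.327464
"LPI(18:1)","LPI","C27H51O12P",598.311814
"LPI(20:4)","LPI","C29H49O12P",620.296164
"SM(34:1)","SM","C39H79N2O6P",702.567575
"SM(34:2)","SM","C39H77N2O6P",700.551925
"SM(36:1)","SM","C41H83N2O6P",730.598875
"SM(36:2)","SM","C41H81N2O6P",728.583225
"SM(38:1)","SM","C43H87N2O6P",758.630175
"SM(38:2)","SM","C43H85N2O6P",756.614525
"SM(40:1)","SM","C45H91N2O6P",786.661475
"SM(40:2)","SM","C45H89N2O6P",784.645825
"SM(42:1)","SM","C47H95N2O6P",814.692775
"SM(42:2)","SM","C47H93N2O6P",812.677125
"Cer(34:1)","Cer","C34H67NO3",537.512095
"Cer(36:1)","Cer","C36H71NO3",565.543395
"Cer(38:1)","Cer","C38H75NO3",593.574695
"Cer(40:1)","Cer","C40H79NO3",621.605995
"Cer(42:1)","Cer","C42H83NO3",649.637296
"Cer(42:2)","Cer","C42H81NO3",647.621645
"CerP(34:1)","CerP","C34H68NO6P",617.478425
"CerP(36:1)","CerP","C36H72NO6P",645.509726
"CerP(38:1)","CerP","C38H76NO6P",673.541026
"CerPE(36:1)","CerPE","C38H77N2O6P",688.551925
"CerPE(38:1)","CerPE","C40H81N2O6P",716.583225
"CerPE(40:1)","CerPE","C42H85N2O6P",744.614525
"CerPI(36:1)","CerPI","C42H82NO11P",807.562549
"CerPI(38:1)","CerPI","C44H86NO11P",835.593849
"HexCer(34:1)","HexCer","C40H77NO8",699.564918
"HexCer(36:1)","HexCer","C42H81NO8",727.596219
"HexCer(38:1)","HexCer","C44H85NO8",755.627519
"HexCer(40:1)","HexCer","C46H89NO8",783.658819
"Hex2Cer(34:1)","Hex2Cer","C46H87NO13",861.617742
"Hex2Cer(38:1)","Hex2Cer","C50H95NO13",917.680342
"CE(14:0)","CE","C41H72O2",596.553232
"CE(16:0)","CE","C43H76O2",624.584532
"CE(16:1)","CE","C43H74O2",622.568882
"CE(18:0)","CE","C45H80O2",652.615832
"CE(18:1)","CE","C45H78O2",650.600182
"CE(18:2)","CE","C45H76O2",648.584532
"CE(18:3)","CE","C45H74O2",646.568882
"CE(20:4)","CE","C47H76O2",672.584532
"CE(22:6)","CE","C49H76O2",696.584532
"TAG(48:1)","TAG","C51H96O6",804.720691
"TAG(48:2)","TAG","C51H94O6",802.705041
"TAG(48:3)","TAG","C51H92O6",800.689391
"TAG(50:1)","TAG","C53H100O6",832.751991
"TAG(50:2)","TAG","C53H98O6",830.736341
"TAG(50:3)","TAG","C53H96O6",828.720691
"TAG(52:1)","TAG","C55H104O6",860.783291
"TAG(52:2)","TAG","C55H102O6",858.767641
"TAG(52:3)","TAG","C55H100O6",856.751991
"TAG(54:1)","TAG","C57H108O6",888.814591
"TAG(54:2)","TAG","C57H106O6",886.798941
"TAG(54:3)","TAG","C57H104O6",884.783291
"TAG(56:1)","TAG","C59H112O6",916.845891
"TAG(56:2)","TAG","C59H110O6",914.830241
"TAG(56:3)","TAG","C59H108O6",912.814591
"DAG(32:0)","DAG","C35H68O5",568.506675
"DAG(34:1)","DAG","C37H70O5",594.522325
"DAG(36:2)","DAG","C39H72O5",620.537975
"DAG(36:4)","DAG","C39H68O5",616.506675
"FFA(16:0)","FFA","C16H32O2",256.24023
"FFA(16:1)","FFA","C16H30O2",254.22458
"FFA(18:0)","FFA","C18H36O2",284.27153
"FFA(18:1)","FFA","C18H34O2",282.25588
"FFA(18:2)","FFA","C18H32O2",280.24023
"FFA(20:4)","FFA","C20H32O2",304.24023
"FFA(22:6)","FFA","C22H32O2",328.24023
"cholesterol","ST","C27H46O",386.354866
"7-ketocholesterol","ST","C27H44O2",400.334131
"ST(27:2;O)","ST","C27H44O",384.339216
"ST(28:1;O)","ST","C28H48O",400.370516
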