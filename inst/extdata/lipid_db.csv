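name,class,carbons,doubleBonds,hydroxyl,formula,prior
PI 38:4,PI,38,4,0,C47H83O13P,1
PI 36:4,PI,36,4,0,C45H79O13P,1
PS 38:3,PS,38,3,0,C44H80NO10P,1
PS 38:4,PS,38,4,0,C44H78NO10P,1
PS 36:1,PS,36,1,0,C42H80NO10P,1
PE 38:4,PE,38,4,0,C43H78NO8P,1
PE O-38:5,PE-O,38,5,0,C43H78NO7P,1
PA 40:5,PA,40,5,0,C43H75O8P,1
PE 36:4,PE,36,4,0,C41H74NO8P,1
PE O-36:5,PE-O,36,5,0,C41H74NO7P,1
LPI 20:4,LPI,20,4,0,C29H49O12P,1
LPI 18:0,LPI,18,0,0,C27H53O12P,1
NeuAcHex2Cer 34:1,NeuAcHex2Cer,34,1,0,C57H104N2O21,1
SHex2Cer 42:2,SHex2Cer,42,2,0,C54H101NO16S,1
PI 40:3,PI,40,3,0,C49H89O13P,1
PI 40:4,PI,40,4,0,C49H87O13P,1
PI 40:5,PI,40,5,0,C49H85O13P,1
PI 40:6,PI,40,6,0,C49H83O13P,1
PI 38:2,PI,38,2,0,C47H87O13P,1
PI 38:3,PI,38,3,0,C47H85O13P,1
PI 36:1,PI,36,1,0,C45H85O13P,1
PI 36:2,PI,36,2,0,C45H83O13P,1
PI 36:3,PI,36,3,0,C45H81O13P,1
PI 34:1,PI,34,1,0,C43H81O13P,1
PS 36:2,PS,36,2,0,C42H78NO10P,1
PS 40:5,PS,40,5,0,C46H80NO10P,1
PS 40:6,PS,40,6,0,C46H78NO10P,1
PG 36:1,PG,36,1,0,C42H81O10P,1
PG 36:2,PG,36,2,0,C42H79O10P,1
PG 34:1,PG,34,1,0,C40H77O10P,1
PE 36:1,PE,36,1,0,C41H80NO8P,1
PE 36:2,PE,36,2,0,C41H78NO8P,1
PE 36:3,PE,36,3,0,C41H76NO8P,1
PE 34:1,PE,34,1,0,C39H76NO8P,1
PE 34:2,PE,34,2,0,C39H74NO8P,1
SHex2Cer 44:2,SHex2Cer,44,2,0,C56H105NO16S,1
SHex2Cer 42:1,SHex2Cer,42,1,0,C54H103NO16S,1
SHex2Cer 42:3,SHex2Cer,42,3,0,C54H99NO16S,1
SHex2Cer 40:1,SHex2Cer,40,1,0,C52H99NO16S,1
SHex2Cer 38:1,SHex2Cer,38,1,0,C50H95NO16S,1
SHex2Cer 36:1,SHex2Cer,36,1,0,C48H91NO16S,1
SHex2Cer 34:1,SHex2Cer,34,1,0,C46H87NO16S,1
SHex2Cer 42:1(OH),SHex2Cer,42,1,1,C54H103NO17S,1
SHexCer 42:1,SHexCer,42,1,0,C48H93NO11S,1
SHexCer 42:2(OH),SHexCer,42,2,1,C48H91NO12S,1
SHexCer 41:1(OH),SHexCer,41,1,1,C47H91NO12S,1
SHexCer 40:1(OH),SHexCer,40,1,1,C46H89NO12S,1
PE O-40:5,PE-O,40,5,0,C45H82NO7P,1
PE O-40:7,PE-O,40,7,0,C45H78NO7P,1
SM 42:2,SM,42,2,0,C47H93N2O6P,1
SM 34:1,SM,34,1,0,C39H79N2O6P,1
PE O-36:2,PE-O,36,2,0,C41H80NO7P,1
PA 38:4,PA,38,4,0,C41H73O8P,1
PA O-38:1,PA-O,38,1,0,C41H81O7P,1
PE O-34:1,PE-O,34,1,0,C39H78NO7P,1
PE O-34:2,PE-O,34,2,0,C39H76NO7P,1
PE 35:1,PE,35,1,0,C40H78NO8P,0
PG 37:2,PG,37,2,0,C43H81O10P,0
PI 37:3,PI,37,3,0,C46H83O13P,0
PS 39:2,PS,39,2,0,C45H84NO10P,0
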