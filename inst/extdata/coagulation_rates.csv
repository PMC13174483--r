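id,reactants,products,k,units,note
1,TF|VII,TF_VII,3.2e6,1/(M*s),"TF + VII association (Hockin et al. 2002, J Biol Chem 277:18322, Table 2)"
2,TF_VII,TF|VII,3.1e-3,1/s,"TF:VII dissociation (Hockin 2002)"
3,TF|VIIa,TF_VIIa,2.3e7,1/(M*s),"TF + VIIa association (Hockin 2002)"
4,TF_VIIa,TF|VIIa,3.1e-3,1/s,"TF:VIIa dissociation (Hockin 2002)"
5,TF_VIIa|VII,TF_VIIa|VIIa,4.4e5,1/(M*s),"VII activation by TF:VIIa (Hockin 2002)"
6,Xa|VII,Xa|VIIa,1.3e7,1/(M*s),"VII activation by Xa (Hockin 2002)"
7,IIa|VII,IIa|VIIa,2.3e4,1/(M*s),"VII activation by thrombin (Hockin 2002)"
8,TF_VIIa|X,TF_VIIa_X,2.5e7,1/(M*s),"X binding to TF:VIIa (Hockin 2002)"
9,TF_VIIa_X,TF_VIIa|X,1.05,1/s,"TF:VIIa:X dissociation (Hockin 2002)"
10,TF_VIIa_X,TF_VIIa_Xa,6,1/s,"X activation within TF:VIIa:X (Hockin 2002)"
11,TF_VIIa|Xa,TF_VIIa_Xa,2.2e7,1/(M*s),"Xa rebinding to TF:VIIa (Hockin 2002)"
12,TF_VIIa_Xa,TF_VIIa|Xa,19,1/s,"TF:VIIa:Xa dissociation (Hockin 2002)"
13,TF_VIIa|IX,TF_VIIa_IX,1e7,1/(M*s),"IX binding to TF:VIIa (Hockin 2002)"
14,TF_VIIa_IX,TF_VIIa|IX,2.4,1/s,"TF:VIIa:IX dissociation (Hockin 2002)"
15,TF_VIIa_IX,TF_VIIa|IXa,1.8,1/s,"IX activation within TF:VIIa:IX (Hockin 2002)"
16,Xa|II,Xa|IIa,7.5e3,1/(M*s),"Prothrombin activation by free Xa (Hockin 2002)"
17,IIa|VIII,IIa|VIIIa,2e7,1/(M*s),"VIII activation by thrombin (Hockin 2002)"
18,VIIIa|IXa,IXa_VIIIa,1e7,1/(M*s),"Intrinsic tenase assembly (Hockin 2002)"
19,IXa_VIIIa,VIIIa|IXa,5e-3,1/s,"Intrinsic tenase dissociation (Hockin 2002)"
20,IXa_VIIIa|X,IXa_VIIIa_X,1e8,1/(M*s),"X binding to intrinsic tenase (Hockin 2002)"
21,IXa_VIIIa_X,IXa_VIIIa|X,1e-3,1/s,"Tenase:X dissociation (Hockin 2002)"
22,IXa_VIIIa_X,IXa_VIIIa|Xa,8.2,1/s,"X activation by intrinsic tenase (Hockin 2002)"
23,VIIIa,VIIIa1L|VIIIa2,6e-3,1/s,"VIIIa subunit dissociation (Hockin 2002)"
24,VIIIa1L|VIIIa2,VIIIa,2.2e4,1/(M*s),"VIIIa subunit reassociation (Hockin 2002)"
25,IXa_VIIIa_X,VIIIa1L|VIIIa2|X|IXa,1e-3,1/s,"Tenase decay via VIIIa subunit loss (Hockin 2002)"
26,IXa_VIIIa,VIIIa1L|VIIIa2|IXa,1e-3,1/s,"Tenase decay via VIIIa subunit loss (Hockin 2002)"
27,IIa|V,IIa|Va,2e7,1/(M*s),"V activation by thrombin (Hockin 2002)"
28,Xa|Va,Xa_Va,4e8,1/(M*s),"Prothrombinase assembly (Hockin 2002)"
29,Xa_Va,Xa|Va,0.2,1/s,"Prothrombinase dissociation (Hockin 2002)"
30,Xa_Va|II,Xa_Va_II,1e8,1/(M*s),"Prothrombin binding to prothrombinase (Hockin 2002)"
31,Xa_Va_II,Xa_Va|II,103,1/s,"Prothrombinase:II dissociation (Hockin 2002)"
32,Xa_Va_II,Xa_Va|mIIa,63.5,1/s,"Meizothrombin generation (Hockin 2002)"
33,mIIa|Xa_Va,IIa|Xa_Va,1.5e7,1/(M*s),"Meizothrombin conversion to thrombin (Hockin 2002)"
34,Xa|TFPI,Xa_TFPI,9e5,1/(M*s),"Xa inhibition by TFPI (Hockin 2002)"
35,Xa_TFPI,Xa|TFPI,3.6e-4,1/s,"Xa:TFPI dissociation (Hockin 2002)"
36,TF_VIIa_Xa|TFPI,TF_VIIa_Xa_TFPI,3.2e8,1/(M*s),"Quaternary TFPI complex formation (Hockin 2002)"
37,TF_VIIa_Xa_TFPI,TF_VIIa_Xa|TFPI,1.1e-4,1/s,"Quaternary TFPI complex dissociation (Hockin 2002)"
38,TF_VIIa|Xa_TFPI,TF_VIIa_Xa_TFPI,5e7,1/(M*s),"TF:VIIa inhibition by Xa:TFPI (Hockin 2002)"
39,Xa|ATIII,Xa_ATIII,1.5e3,1/(M*s),"Xa neutralisation by antithrombin (Hockin 2002)"
40,mIIa|ATIII,mIIa_ATIII,7.1e3,1/(M*s),"Meizothrombin neutralisation by antithrombin (Hockin 2002)"
41,IXa|ATIII,IXa_ATIII,4.9e2,1/(M*s),"IXa neutralisation by antithrombin (Hockin 2002)"
42,IIa|ATIII,IIa_ATIII,7.1e3,1/(M*s),"Thrombin neutralisation by antithrombin (TAT complex; Hockin 2002)"
43,TF_VIIa|ATIII,TF_VIIa_ATIII,2.3e2,1/(M*s),"TF:VIIa neutralisation by antithrombin (Hockin 2002)"
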