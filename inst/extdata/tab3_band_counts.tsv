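model	ancestry	label	controls	cases
lasso	european	0-5	9880	12
lasso	european	5-10	9870	24
lasso	european	10-20	19733	53
lasso	european	20-40	39468	104
lasso	european	40-60	39457	115
lasso	european	60-80	39425	147
lasso	european	80-90	19699	87
lasso	european	90-95	9842	51
lasso	european	95-100	9830	64
lasso	east_asian	0-5	278	106
lasso	east_asian	5-10	271	112
lasso	east_asian	10-20	487	280
lasso	east_asian	20-40	993	541
lasso	east_asian	40-60	967	566
lasso	east_asian	60-80	941	593
lasso	east_asian	80-90	466	301
lasso	east_asian	90-95	214	169
lasso	east_asian	95-100	211	173
lasso	african	0-5	35	19
lasso	african	5-10	41	13
lasso	african	10-20	81	26
lasso	african	20-40	154	60
lasso	african	40-60	133	81
lasso	african	60-80	136	78
lasso	african	80-90	63	44
lasso	african	90-95	34	20
lasso	african	95-100	27	27
enet	european	0-5	9876	17
enet	european	5-10	9876	17
enet	european	10-20	19740	45
enet	european	20-40	39453	120
enet	european	40-60	39471	101
enet	european	60-80	39413	159
enet	european	80-90	19695	91
enet	european	90-95	9841	52
enet	european	95-100	9839	55
enet	east_asian	0-5	277	107
enet	east_asian	5-10	271	112
enet	east_asian	10-20	497	270
enet	east_asian	20-40	967	567
enet	east_asian	40-60	1000	533
enet	east_asian	60-80	926	608
enet	east_asian	80-90	457	310
enet	east_asian	90-95	226	157
enet	east_asian	95-100	207	177
enet	african	0-5	35	19
enet	african	5-10	41	13
enet	african	10-20	81	26
enet	african	20-40	154	60
enet	african	40-60	133	81
enet	african	60-80	136	78
enet	african	80-90	63	44
enet	african	90-95	34	20
enet	african	95-100	27	27
stepwise	european	0-5	9880	13
stepwise	european	5-10	9874	19
stepwise	european	10-20	19742	44
stepwise	european	20-40	39470	102
stepwise	european	40-60	39440	132
stepwise	european	60-80	39414	158
stepwise	european	80-90	19697	88
stepwise	european	90-95	9853	41
stepwise	european	95-100	9834	60
stepwise	east_asian	0-5	254	130
stepwise	east_asian	5-10	268	115
stepwise	east_asian	10-20	494	273
stepwise	east_asian	20-40	970	564
stepwise	east_asian	40-60	979	564
stepwise	east_asian	60-80	951	583
stepwise	east_asian	80-90	456	311
stepwise	east_asian	90-95	236	147
stepwise	east_asian	95-100	220	164
stepwise	african	0-5	40	14
stepwise	african	5-10	43	11
stepwise	african	10-20	80	27
stepwise	african	20-40	142	72
stepwise	african	40-60	146	68
stepwise	african	60-80	130	84
stepwise	african	80-90	61	46
stepwise	african	90-95	35	19
stepwise	african	95-100	27	27
s4	european	0-5	9957	16
s4	european	5-10	9888	15
s4	european	10-20	19812	51
s4	european	20-40	39435	113
s4	european	40-60	39512	117
s4	european	60-80	39316	158
s4	european	80-90	19718	77
s4	european	90-95	9791	45
s4	european	95-100	9775	65
s4	east_asian	0-5	279	105
s4	east_asian	5-10	254	129
s4	east_asian	10-20	489	278
s4	east_asian	20-40	1013	521
s4	east_asian	40-60	961	572
s4	east_asian	60-80	950	584
s4	east_asian	80-90	434	333
s4	east_asian	90-95	233	150
s4	east_asian	95-100	215	169
s4	african	0-5	38	16
s4	african	5-10	41	13
s4	african	10-20	81	26
s4	african	20-40	156	58
s4	african	40-60	134	80
s4	african	60-80	137	77
s4	african	80-90	61	46
s4	african	90-95	30	24
s4	african	95-100	26	28
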