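gene	age	p_er_neg	p_tn_given_er_neg
population	20	0.2	0.33
population	25	0.2	0.33
population	30	0.2	0.33
population	35	0.2	0.33
population	40	0.2	0.33
population	45	0.2	0.33
population	50	0.2	0.33
population	55	0.2	0.33
population	60	0.2	0.33
population	65	0.2	0.33
population	70	0.2	0.33
population	75	0.2	0.33
population	79	0.2	0.33
BRCA1	20	0.8454	0.7
BRCA1	25	0.8318	0.7
BRCA1	30	0.8174	0.7
BRCA1	35	0.802	0.7
BRCA1	40	0.7856	0.7
BRCA1	45	0.7683	0.7
BRCA1	50	0.75	0.7
BRCA1	55	0.7308	0.7
BRCA1	60	0.7107	0.7
BRCA1	65	0.6897	0.7
BRCA1	70	0.6679	0.7
BRCA1	75	0.6453	0.7
BRCA1	79	0.6268	0.7
BRCA2	20	0.3103	0.4
BRCA2	25	0.2997	0.4
BRCA2	30	0.2893	0.4
BRCA2	35	0.2792	0.4
BRCA2	40	0.2692	0.4
BRCA2	45	0.2595	0.4
BRCA2	50	0.25	0.4
BRCA2	55	0.2407	0.4
BRCA2	60	0.2317	0.4
BRCA2	65	0.2229	0.4
BRCA2	70	0.2144	0.4
BRCA2	75	0.2061	0.4
BRCA2	79	0.1996	0.4
PALB2	20	0.5985	0.6
PALB2	25	0.5743	0.6
PALB2	30	0.5497	0.6
PALB2	35	0.5248	0.6
PALB2	40	0.4998	0.6
PALB2	45	0.4749	0.6
PALB2	50	0.45	0.6
PALB2	55	0.4254	0.6
PALB2	60	0.4012	0.6
PALB2	65	0.3774	0.6
PALB2	70	0.3542	0.6
PALB2	75	0.3317	0.6
PALB2	79	0.3142	0.6
CHEK2	20	0.2168	0.25
CHEK2	25	0.2043	0.25
CHEK2	30	0.1924	0.25
CHEK2	35	0.181	0.25
CHEK2	40	0.1701	0.25
CHEK2	45	0.1598	0.25
CHEK2	50	0.15	0.25
CHEK2	55	0.1407	0.25
CHEK2	60	0.1319	0.25
CHEK2	65	0.1235	0.25
CHEK2	70	0.1156	0.25
CHEK2	75	0.1082	0.25
CHEK2	79	0.1025	0.25
ATM	20	0.2816	0.35
ATM	25	0.2667	0.35
ATM	30	0.2523	0.35
ATM	35	0.2384	0.35
ATM	40	0.2251	0.35
ATM	45	0.2123	0.35
ATM	50	0.2	0.35
ATM	55	0.1883	0.35
ATM	60	0.1771	0.35
ATM	65	0.1664	0.35
ATM	70	0.1563	0.35
ATM	75	0.1466	0.35
ATM	79	0.1393	0.35
BARD1	20	0.8971	0.75
BARD1	25	0.8824	0.75
BARD1	30	0.866	0.75
BARD1	35	0.8476	0.75
BARD1	40	0.8272	0.75
BARD1	45	0.8047	0.75
BARD1	50	0.78	0.75
BARD1	55	0.7532	0.75
BARD1	60	0.7243	0.75
BARD1	65	0.6933	0.75
BARD1	70	0.6605	0.75
BARD1	75	0.6261	0.75
BARD1	79	0.5976	0.75
RAD51C	20	0.8635	0.72
RAD51C	25	0.8448	0.72
RAD51C	30	0.8241	0.72
RAD51C	35	0.8013	0.72
RAD51C	40	0.7763	0.72
RAD51C	45	0.7492	0.72
RAD51C	50	0.72	0.72
RAD51C	55	0.6888	0.72
RAD51C	60	0.6558	0.72
RAD51C	65	0.6212	0.72
RAD51C	70	0.5853	0.72
RAD51C	75	0.5485	0.72
RAD51C	79	0.5186	0.72
RAD51D	20	0.8516	0.7
RAD51D	25	0.8316	0.7
RAD51D	30	0.8096	0.7
RAD51D	35	0.7854	0.7
RAD51D	40	0.759	0.7
RAD51D	45	0.7305	0.7
RAD51D	50	0.7	0.7
RAD51D	55	0.6676	0.7
RAD51D	60	0.6335	0.7
RAD51D	65	0.598	0.7
RAD51D	70	0.5615	0.7
RAD51D	75	0.5243	0.7
RAD51D	79	0.4943	0.7
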