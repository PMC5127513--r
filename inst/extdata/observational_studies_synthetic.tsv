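METABOLITE	STUDY	EFFECT	L95	U95	N_CASES	N_NONCASES
isoleucine	cohort_A	1.185337	0.793754	1.770100	332	720
isoleucine	cohort_B	1.246111	0.834451	1.860855	332	720
isoleucine	cohort_C	1.284060	0.859863	1.917526	332	720
isoleucine	cohort_D	1.336464	0.894955	1.995782	332	720
isoleucine	cohort_E	1.377165	0.922211	2.056563	332	720
isoleucine	cohort_F	1.447774	0.969493	2.162005	332	719
leucine	cohort_A	1.103902	0.738594	1.649890	332	720
leucine	cohort_B	1.160500	0.776462	1.734482	332	720
leucine	cohort_C	1.195842	0.800109	1.787305	332	720
leucine	cohort_D	1.244646	0.832762	1.860246	332	720
leucine	cohort_E	1.282551	0.858124	1.916899	332	720
leucine	cohort_F	1.348309	0.902121	2.015181	332	719
valine	cohort_A	1.212482	0.777403	1.891058	332	720
valine	cohort_B	1.274647	0.817261	1.988014	332	720
valine	cohort_C	1.313466	0.842150	2.048558	332	720
valine	cohort_D	1.367070	0.876519	2.132162	332	720
valine	cohort_E	1.408703	0.903213	2.197095	332	720
valine	cohort_F	1.480929	0.949522	2.309743	332	719
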