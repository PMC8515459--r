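# Published cohort summary of the DiaGene and Hoorn DCS type 2 diabetes
# cohorts: participant counts, complication case/total counts with the
# printed percentages, and lipid means (mmol/L). Prevalent percentages are
# printed against the full cohort n; incident percentages against the shown
# risk-set totals.
cohort	item	value
diagene	n_participants	1815
dcs	n_participants	1518
diagene	prevalent_cvd_cases	628
diagene	prevalent_cvd_total	1669
diagene	prevalent_cvd_pct	34.6
dcs	prevalent_cvd_cases	288
dcs	prevalent_cvd_total	1518
dcs	prevalent_cvd_pct	19.0
diagene	incident_cvd_cases	104
diagene	incident_cvd_total	1034
diagene	incident_cvd_pct	10.1
dcs	incident_cvd_cases	97
dcs	incident_cvd_total	1220
dcs	incident_cvd_pct	8.0
diagene	prevalent_nephropathy_cases	367
diagene	prevalent_nephropathy_total	1621
diagene	prevalent_nephropathy_pct	20.2
dcs	prevalent_nephropathy_cases	236
dcs	prevalent_nephropathy_total	1518
dcs	prevalent_nephropathy_pct	15.5
diagene	incident_nephropathy_cases	244
diagene	incident_nephropathy_total	1214
diagene	incident_nephropathy_pct	20.1
dcs	incident_nephropathy_cases	158
dcs	incident_nephropathy_total	1272
dcs	incident_nephropathy_pct	12.4
diagene	prevalent_retinopathy_cases	291
diagene	prevalent_retinopathy_total	1714
diagene	prevalent_retinopathy_pct	16.0
dcs	prevalent_retinopathy_cases	214
dcs	prevalent_retinopathy_total	1503
dcs	prevalent_retinopathy_pct	14.2
diagene	incident_retinopathy_cases	219
diagene	incident_retinopathy_total	1361
diagene	incident_retinopathy_pct	16.1
dcs	incident_retinopathy_cases	126
dcs	incident_retinopathy_total	1278
dcs	incident_retinopathy_pct	9.9
diagene	total_cholesterol_mean	4.3
diagene	hdl_mean	1.2
diagene	non_hdl_mean	3.1
dcs	total_cholesterol_mean	4.6
dcs	hdl_mean	1.2
dcs	non_hdl_mean	3.5
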