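strategy_type,label,colonoscopies_per_1000,qalys_gained_per_1000,efficient
reference,FIT_only,1243,156.77,yes
risk_score,10%_74,1268,159.73,yes
risk_score,20%_74,1294,162.05,yes
risk_score,30%_74,1320,164.12,yes
risk_score,40%_74,1346,165.96,yes
risk_score,50%_74,1373,167.69,no
risk_score,60%_74,1401,169.50,yes
risk_score,70%_74,1430,171.36,yes
fit_based,FIT10_x,1458,163.72,no
risk_score,80%_74,1460,172.88,yes
risk_score,90%_74,1489,174.25,yes
age_based,Age_74,1519,175.55,yes
fit_based,FIT10_74,1654,176.92,no
risk_score,60%_64:74,1654,179.26,yes
risk_score,40%_54:64:74,1722,181.09,yes
risk_score,70%_64:74,1728,181.22,yes
risk_score,80%_64:74,1804,182.83,yes
risk_score,50%_54:64:74,1859,183.97,yes
risk_score,90%_64:74,1884,184.40,no
age_based,Age_64,1965,185.69,no
risk_score,60%_54:64:74,2001,186.45,yes
fit_based,FIT10_64,2016,185.30,no
reference,50/50,2023,169.52,no
risk_score,50%_54:64,2032,186.96,yes
risk_score,60%_54:64,2161,188.89,yes
risk_score,70%_54:64:74,2169,188.98,yes
risk_score,70%_54:64,2290,190.33,yes
risk_score,80%_54:64:74,2339,190.80,no
risk_score,80%_54:64,2421,191.66,no
risk_score,90%_54:64:74,2515,192.82,yes
risk_score,90%_54:64,2559,193.26,yes
age_based,Age_54,2696,194.56,yes
fit_based,FIT10_54,2698,194.50,no
reference,COL_only,2804,182.28,no
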