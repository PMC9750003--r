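name,base,low,high,family,units,group
intervention_cost,5873.8000000000002,4992.7299999999996,6754.8599999999997,gamma,USD,cost
annual_income,1354.6800000000001,469.16000000000003,3054.5500000000002,gamma,USD/year,cost
rehabilitation_cost,27.030000000000001,22.969999999999999,31.079999999999998,gamma,USD/year,cost
prosthetic_cost,672.5,400,945,gamma,USD,cost
episode_cost,15.19,12.91,17.469999999999999,gamma,USD,cost
cfr_pre_rti,0.031399999999999997,0.021465070742162223,0.041334929257837771,beta,probability,cfr_pre
cfr_pre_pph,0.0172,0,0.034570241829197983,beta,probability,cfr_pre
cfr_pre_asthma,0.0111,0,0.026749546315025595,beta,probability,cfr_pre
cfr_pre_paediatric_pneumonia,0.063200000000000006,0.036657280468330992,0.089742719531669013,beta,probability,cfr_pre
cfr_pre_paediatric_diarrhoea,0.026700000000000002,0.0070393697009162176,0.046360630299083785,beta,probability,cfr_pre
or_rti,0.26500000000000001,0.113,0.62160000000000004,beta,ratio,odds_ratio
or_pph,0.00033500000000000001,0,3.3760000000000001e+37,beta,ratio,odds_ratio
or_asthma,0.0036700000000000001,0,3.6609999999999998e+34,beta,ratio,odds_ratio
or_paediatric_pneumonia,0.42299999999999999,0.2392,0.74809999999999999,beta,ratio,odds_ratio
or_paediatric_diarrhoea,0.57420000000000004,0.14949999999999999,2.2048000000000001,beta,ratio,odds_ratio
p_no_disability,0.96199999999999997,0.81799999999999995,0.99199999999999999,beta,probability,disability
p_amputation,0.78800000000000003,0.67000000000000004,0.90700000000000003,beta,probability,disability
p_neuro,0.21199999999999999,0.17899999999999999,0.24299999999999999,beta,probability,disability
p_rehab,0.115,0.098000000000000004,0.13300000000000001,beta,probability,disability
weight_amputation,0.27500000000000002,0.23400000000000001,0.316,beta,DALY weight,daly_weight
weight_neuro,0.35899999999999999,0.30499999999999999,0.41299999999999998,beta,DALY weight,daly_weight
discount_rate,0.035000000000000003,0,0.050000000000000003,beta,fraction/year,assumption
time_horizon,55,46.409999999999997,62.789999999999999,lognormal,years,assumption
life_expectancy,68.599999999999994,,,fixed,years,assumption
fx_rate,3675,,,fixed,UGX/USD,assumption
startup_cost,1683,,,fixed,USD,intervention_component
bec_training_cost,3515,,,fixed,USD,intervention_component
triage_tool_cost,172,,,fixed,USD,intervention_component
checklist_tool_cost,503,,,fixed,USD,intervention_component
share_rti,0.55000000000000004,0.41250000000000003,0.6875,fixed,probability,cohort_share
share_pph,0.10000000000000001,,,fixed,probability,cohort_share
share_asthma,0.080000000000000002,,,fixed,probability,cohort_share
share_paediatric_pneumonia,0.14999999999999999,,,fixed,probability,cohort_share
share_paediatric_diarrhoea,0.12,,,fixed,probability,cohort_share
age_rti,26,,,fixed,years,median_age
age_pph,26,,,fixed,years,median_age
age_asthma,26,,,fixed,years,median_age
age_paediatric_pneumonia,2,,,fixed,years,median_age
age_paediatric_diarrhoea,2,,,fixed,years,median_age
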