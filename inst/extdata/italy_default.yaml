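schema: 1
efficacy:
  rve_hd_vs_sd_cases: 0.242
  rve_hd_vs_sd_hosp: 0.182
  rve_aqiv_vs_sd_cases: 0.0
  rve_aqiv_vs_sd_hosp: 0.0
  preventable_fraction_cases: 0.392918932414777
  preventable_fraction_hosp: 0.506460797196671
  preventable_fraction_deaths: 0.392918932414777
  risk_death_scale: 1.0
epi:
  cohort_size: 8089799.999999999068677
  attack_rate: 0.090983213429257
  p_gp_given_case: 0.386000141297437
  p_er_given_case: 0.008181665027254
  p_hosp_influenza_given_case: 0.006
  cardioresp_hosp_rate: 0.058699102573611
  excess_mortality_per_100k: 75.76207075576653
  coverage: 0.582
costs:
  price_aqiv: 15.449999999999999
  price_hd: 32.270000000000003
  cost_gp_visit: 20.66
  cost_er_visit: 241.77000000000001
  cost_hospitalization: 4035.320000000000164
  cost_otc_per_case: 5.0
  admin_cost: 0.0
utilities:
  baseline_utility_by_age:
    '65': 0.89
    '66': 0.886
    '67': 0.882
    '68': 0.878
    '69': 0.874
    '70': 0.87
    '71': 0.866
    '72': 0.862
    '73': 0.858
    '74': 0.854
    '75': 0.85
    '76': 0.846
    '77': 0.842
    '78': 0.838
    '79': 0.834
    '80': 0.83
    '81': 0.826
    '82': 0.822
    '83': 0.818
    '84': 0.814
    '85': 0.81
    '86': 0.806
    '87': 0.802
    '88': 0.798
    '89': 0.794
    '90': 0.79
    '91': 0.786
    '92': 0.782
    '93': 0.778
    '94': 0.774
    '95': 0.77
    '96': 0.766
    '97': 0.762
    '98': 0.758
    '99': 0.754
    '100': 0.75
  utility_influenza_episode: 0.5
  utility_hospitalized: 0.35
  influenza_duration_days: 6.0
  hospitalization_duration_days: 5.2
life_table:
  ages:
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  annual_survival_prob:
  - 0.991
  - 0.990053461737319
  - 0.989007375176558
  - 0.987851270731816
  - 0.986573577721229
  - 0.985161508563699
  - 0.983600930796485
  - 0.981876225632766
  - 0.979970131643568
  - 0.977863571999587
  - 0.975535463543869
  - 0.972962505784482
  - 0.970118947695371
  - 0.966976329991427
  - 0.963503200298398
  - 0.959664798366957
  - 0.955422708180444
  - 0.950734473474455
  - 0.945553172820284
  - 0.939826950019487
  - 0.933498495109624
  - 0.926504470786891
  - 0.918774878505093
  - 0.910232357906667
  - 0.900791412574226
  - 0.890357554353669
  - 0.878826357684985
  - 0.866082414476145
  - 0.851998179060127
  - 0.836432691675012
  - 0.819230167691311
  - 0.800218438467025
  - 0.779207228226016
  - 0.755986249714079
  - 0.730323099573427
  - 0.0
  discount_rate: 0.03
scenario:
  hospitalization_approach: cardiorespiratory
  aqiv_scenario_label: s1_0pct
  wtp_per_qaly: 30000.0
age_distribution:
  '65': 0.089576998917665
  '66': 0.081867212793861
  '67': 0.074820998823546
  '68': 0.06838124413798
  '69': 0.062495751505345
  '70': 0.057116816247697
  '71': 0.052200839572176
  '72': 0.047707975182352
  '73': 0.043601806305298
  '74': 0.039849050516567
  '75': 0.036419289970539
  '76': 0.033284724849511
  '77': 0.030419948033141
  '78': 0.027801739161817
  '79': 0.025408876424761
  '80': 0.023221964547292
  '81': 0.021223277583033
  '82': 0.019396615236802
  '83': 0.01772717155362
  '84': 0.016201414909507
  '85': 0.014806978331316
  '86': 0.013532559256625
  '87': 0.012367827921161
  '88': 0.011303343631217
  '89': 0.010330478242406
  '90': 0.009441346224501
  '91': 0.008628740745514
  '92': 0.007886075256946
  '93': 0.007207330106719
  '94': 0.006587003747074
  '95': 0.00602006814195
  '96': 0.005501928012386
  '97': 0.005028383589637
  '98': 0.004595596574075
  '99': 0.004200059023973
  '100': 0.003838564921989
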