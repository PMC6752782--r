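item,n,agreement,kappa,ci_low,ci_high
allocation_concealment,73,90.4,0.818,0.681,0.944
random_sequence_generation,74,85.1,0.686,0.517,0.787
blinding_outcome_assessment,57,70.2,0.533,0.342,0.702
selective_reporting,69,66.7,0.450,0.275,0.617
incomplete_outcome_data,73,61.6,0.365,0.201,0.530
other_bias,36,66.7,0.314,0.059,0.558
blinding_participants_personnel,28,89.3,-0.037,-0.091,0.000
blinding_participants,14,92.9,NA,NA,NA
blinding_personnel,14,100.0,NA,NA,NA
blinding_outcome_subjective,0,NA,NA,NA,NA
blinding_outcome_objective,0,NA,NA,NA,NA
blinding_participants_personnel_outcome,0,NA,NA,NA,NA
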