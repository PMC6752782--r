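item,n1_main,percent_main,n1_sens1,percent_sens1,n1_sens2,percent_sens2
random_sequence_generation,738,51,1341,93,738,88
allocation_concealment,517,36,1316,92,517,81
blinding_participants_personnel,82,14,163,27,82,16
blinding_participants,75,14,153,28,75,16
blinding_personnel,51,12,103,25,51,14
blinding_outcome_assessment,318,29,693,64,318,45
blinding_outcome_subjective,20,24,28,34,20,27
blinding_outcome_objective,57,53,90,83,57,76
blinding_participants_personnel_outcome,72,33,166,76,72,58
incomplete_outcome_data,743,52,1082,76,743,68
selective_reporting,628,48,1145,87,628,79
other_bias,490,56,763,88,490,82
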