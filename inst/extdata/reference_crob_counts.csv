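item,low,unclear,high
random_sequence_generation,738,603,100
allocation_concealment,517,799,122
blinding_participants_personnel,82,81,438
blinding_participants,75,78,385
blinding_personnel,51,52,312
blinding_outcome_assessment,318,375,388
blinding_outcome_subjective,20,8,54
blinding_outcome_objective,57,33,18
blinding_participants_personnel_outcome,72,94,52
incomplete_outcome_data,743,339,350
selective_reporting,628,517,169
other_bias,490,273,109
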