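pedro_item,crob_item,scheme,n,agreement,kappa,ci_low,ci_high
random_allocation,random_sequence_generation,main,1441,53.8,0.054,0.031,0.082
concealed_allocation,allocation_concealment,main,1438,81.2,0.582,0.495,0.656
subject_blinding,blinding_participants,main,538,90.7,0.479,0.250,0.687
therapist_blinding,blinding_personnel,main,415,89.2,0.251,0.025,0.537
assessor_blinding,blinding_outcome_assessment,main,1081,78.8,0.519,0.427,0.603
follow_up,incomplete_outcome_data,main,1432,63.0,0.254,0.191,0.308
random_allocation,random_sequence_generation,sens1,1441,94.9,0.467,0.329,0.595
concealed_allocation,allocation_concealment,sens1,1438,39.9,0.067,0.042,0.095
subject_blinding,blinding_participants,sens1,538,76.2,0.227,0.085,0.424
therapist_blinding,blinding_personnel,sens1,415,76.6,0.110,0.000,0.362
assessor_blinding,blinding_outcome_assessment,sens1,1081,53.4,0.138,0.047,0.242
follow_up,incomplete_outcome_data,sens1,1432,66.1,0.238,0.171,0.303
random_allocation,random_sequence_generation,sens2,838,91.9,0.473,0.329,0.610
concealed_allocation,allocation_concealment,sens2,639,73.7,0.421,0.300,0.531
subject_blinding,blinding_participants,sens2,460,89.1,0.471,0.248,0.680
therapist_blinding,blinding_personnel,sens2,363,87.6,0.245,0.023,0.554
assessor_blinding,blinding_outcome_assessment,sens2,706,74.6,0.490,0.386,0.593
follow_up,incomplete_outcome_data,sens2,1093,69.1,0.322,0.254,0.383
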