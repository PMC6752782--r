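item,yes,n_total
eligibility,1170,1442
random_allocation,1399,1442
concealed_allocation,473,1442
baseline_comparability,1153,1442
subject_blinding,70,1442
therapist_blinding,26,1442
assessor_blinding,529,1442
follow_up,877,1442
intention_to_treat,465,1442
between_group_comparisons,1372,1442
point_measures,1311,1442
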