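pa-instance 1
n_patients 6
n_doctors 3
est_time 9.1587469133082777 5.0077746936585754 12.659125594655052 5.2107186254579574 5.9703466494102031 19.322738382034004
candidates all
# spec n_patients=6 n_doctors=3 t_min=5 t_max=20 candidate_mode=all k=3 integer_times=FALSE seed=11
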