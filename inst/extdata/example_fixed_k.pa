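pa-instance 1
n_patients 8
n_doctors 5
est_time 6.0404137370642275 17.266627980861813 19.13932598545216 9.0407281450461596 7.5402218487579376 5.5084343370981514 7.6817750628106296 14.624980483204126
candidates list
1: 2 3 4
2: 1 2 5
3: 1 2 4
4: 1 2 3
5: 1 4 5
6: 2 3 5
7: 2 3 5
8: 1 4 5
# spec n_patients=8 n_doctors=5 t_min=5 t_max=20 candidate_mode=fixed-k k=3 integer_times=FALSE seed=12
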