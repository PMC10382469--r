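# Synthetic stand-in for the study's per-subject behavioral table (the
# original is published only as an image). Integer correct-block counts,
# constructed so group means equal the published 12.5 (MT) and 3.3 (NT)
# exactly; SDs are the closest achievable by integers in [0, 14]: 1.51 and
# 2.00 versus the published 1.5 and 2.03 (SD = 2.03 with mean 3.3 is
# infeasible for ten integers by a sum-of-squares parity argument).
subject	group	correct_blocks
MT01	MT	10
MT02	MT	10
MT03	MT	12
MT04	MT	12
MT05	MT	13
MT06	MT	13
MT07	MT	13
MT08	MT	14
MT09	MT	14
MT10	MT	14
NT01	NT	0
NT02	NT	1
NT03	NT	2
NT04	NT	3
NT05	NT	3
NT06	NT	4
NT07	NT	4
NT08	NT	4
NT09	NT	5
NT10	NT	7
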