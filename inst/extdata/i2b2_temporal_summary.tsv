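relation_type	training	test
Temporal relations	33635	27736
BEFORE	13467	10789
AFTER	2211	1941
SIMULTANEOUS	4725	4142
OVERLAP	7061	4877
BEGUN_BY	996	788
ENDED_BY	797	688
DURING	1037	875
BEFORE_OVERLAP	3249	3636
Unlabeled	92	0
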