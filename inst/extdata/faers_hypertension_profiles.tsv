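drug	atc_class	ade_indices	gl_cluster
macitentan	AHAs	1-15,17	1
bosentan	AHAs	1,2,4-15	1
epoprostenol	ATAs	1,2,4-9,11,12,15	1
selexipag	ATAs	2,4-12	1
sildenafil	UAs	1,2,4-12	1
tadalafil	UAs	1,2,4-12	1
beraprost	ATAs	1,2,5-9	1
nifedipine	CCBs	1-3,15,16	2
candesartan	ARBs	1,3,14,16	2
althiazide/spironolactone	COMBs	4,10,11	3
rilmenidine	AHAs	4,10	3
bisoprolol	BBAs	1,2,14	4
lercanidipine	CCBs	1,14	4
imidapril	ACEIs	1-3	5
azelnidipine	CCBs	1,3	5
azilsartan kamedoxomil	ARBs	1,3	5
benidipine	CCBs	1,2	5
cilnidipine	CCBs	1,2	5
telmisartan	ARBs	1,3	5
bendroflumethiazide	TDAs	3,13	6
doxazosin	AHAs	3,13	6
nicardipine	CCBs	3,13	6
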