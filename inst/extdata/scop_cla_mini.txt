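# mini SCOP dir.cla-style fixture (synthetic)
d1dlwa_	1dlw	A:1-116	a.1.1.1	14982	cl=46456,cf=46457,sf=46458,fa=46459,dm=46460,sp=46461,px=14982
d1idra_	1idr	A:	a.1.1.2	15274	cl=46456,cf=46457,sf=46458,fa=46463,dm=46464,sp=46465,px=15274
d2gkma_	2gkm	A:2-130,B:5-20	b.121.4.2	21043	cl=48724,cf=49000,sf=49001,fa=49002,dm=49003,sp=49004,px=21043
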