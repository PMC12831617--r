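method	rank	feature_id
selectkbest	1	glutamic acid
selectkbest	2	P02743
selectkbest	3	P00747
selectkbest	4	P13598
selectkbest	5	P19320
elasticnet	1	P05160
elasticnet	2	P13591
elasticnet	3	glutamic acid
elasticnet	4	P35858
elasticnet	5	lactic acid
svmrfe	1	glutamic acid
svmrfe	2	P02763
svmrfe	3	lactic acid
svmrfe	4	P02743
svmrfe	5	behenic acid
transformer_rfe	1	glutamic acid
transformer_rfe	2	lactic acid
transformer_rfe	3	P10909
transformer_rfe	4	33101
transformer_rfe	5	P13796
rf	1	behenic acid
rf	2	glutamic acid
rf	3	alpha-d-glucosamine 1-phosphate
rf	4	P05160
rf	5	P00747
moiner	1	P27169
moiner	2	73514
moiner	3	64403
moiner	4	P02771
moiner	5	P08519
mogonet	1	P0C0L4
mogonet	2	P22891
mogonet	3	P01877
mogonet	4	P02655
mogonet	5	glutamic acid
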