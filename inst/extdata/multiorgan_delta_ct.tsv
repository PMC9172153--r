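organ	target	genotype	replicate	delta_ct
Liver	Gas2l1	WT	1	2.1
Liver	Gas2l1	WT	2	5.6
Liver	Gas2l1	WT	3	2.7
Liver	Gas2l1	MUT	1	>9.4
Liver	Gas2l1	MUT	2	2.2
Liver	Gas2l1	MUT	3	1.1
Liver	Osbpl2	WT	1	6.0
Liver	Osbpl2	WT	2	5.5
Liver	Osbpl2	WT	3	5.6
Liver	Osbpl2	MUT	1	-1.5
Liver	Osbpl2	MUT	2	0.2
Liver	Osbpl2	MUT	3	0.1
Liver	Ndufs7	WT	1	15.6
Liver	Ndufs7	WT	2	17.1
Liver	Ndufs7	WT	3	15.3
Liver	Ndufs7	MUT	1	>12.4
Liver	Ndufs7	MUT	2	11.8
Liver	Ndufs7	MUT	3	12.0
Liver	Wrap73	WT	1	7.2
Liver	Wrap73	WT	2	8.9
Liver	Wrap73	WT	3	9.1
Liver	Wrap73	MUT	1	-0.2
Liver	Wrap73	MUT	2	1.2
Liver	Wrap73	MUT	3	1.7
Testis	Gas2l1	WT	1	1.5
Testis	Gas2l1	WT	2	>6.4
Testis	Gas2l1	WT	3	>6.1
Testis	Gas2l1	MUT	1	0.9
Testis	Gas2l1	MUT	2	1.5
Testis	Gas2l1	MUT	3	2.1
Testis	Osbpl2	WT	1	2.3
Testis	Osbpl2	WT	2	5.2
Testis	Osbpl2	WT	3	4.3
Testis	Osbpl2	MUT	1	0.6
Testis	Osbpl2	MUT	2	1.6
Testis	Osbpl2	MUT	3	2.6
Testis	Ndufs7	WT	1	>13
Testis	Ndufs7	WT	2	>16.8
Testis	Ndufs7	WT	3	>18.1
Testis	Ndufs7	MUT	1	11.5
Testis	Ndufs7	MUT	2	9.7
Testis	Ndufs7	MUT	3	17.0
Testis	Wrap73	WT	1	6.2
Testis	Wrap73	WT	2	7.7
Testis	Wrap73	WT	3	7.9
Testis	Wrap73	MUT	1	2.9
Testis	Wrap73	MUT	2	3.0
Testis	Wrap73	MUT	3	3.5
Brain	Gas2l1	WT	1	6.7
Brain	Gas2l1	WT	2	>6.8
Brain	Gas2l1	WT	3	>5.5
Brain	Gas2l1	MUT	1	1.1
Brain	Gas2l1	MUT	2	1.2
Brain	Gas2l1	MUT	3	6.7
Brain	Osbpl2	WT	1	4.4
Brain	Osbpl2	WT	2	7.0
Brain	Osbpl2	WT	3	6.5
Brain	Osbpl2	MUT	1	-0.7
Brain	Osbpl2	MUT	2	1.5
Brain	Osbpl2	MUT	3	0.9
Brain	Ndufs7	WT	1	>13.8
Brain	Ndufs7	WT	2	>18.1
Brain	Ndufs7	WT	3	>18.3
Brain	Ndufs7	MUT	1	10.7
Brain	Ndufs7	MUT	2	11.9
Brain	Ndufs7	MUT	3	17.5
Brain	Wrap73	WT	1	10.1
Brain	Wrap73	WT	2	>13
Brain	Wrap73	WT	3	>12.9
Brain	Wrap73	MUT	1	3.6
Brain	Wrap73	MUT	2	3.4
Brain	Wrap73	MUT	3	5.7
Heart	Pick1	WT	1	>8.6
Heart	Pick1	WT	2	>7.0
Heart	Pick1	WT	3	>2.6
Heart	Pick1	MUT	1	5.0
Heart	Pick1	MUT	2	6.2
Heart	Pick1	MUT	3	4.0
Heart	Gas2l1	WT	1	3.3
Heart	Gas2l1	WT	2	>6.3
Heart	Gas2l1	WT	3	>6
Heart	Gas2l1	MUT	1	-1.3
Heart	Gas2l1	MUT	2	1.5
Heart	Gas2l1	MUT	3	2.5
Heart	Osbpl2	WT	1	5.2
Heart	Osbpl2	WT	2	8.2
Heart	Osbpl2	WT	3	>10.6
Heart	Osbpl2	MUT	1	-0.5
Heart	Osbpl2	MUT	2	0.9
Heart	Osbpl2	MUT	3	3.9
Heart	Ndufs7	WT	1	15.8
Heart	Ndufs7	WT	2	>20.9
Heart	Ndufs7	WT	3	>20.3
Heart	Ndufs7	MUT	1	7.5
Heart	Ndufs7	MUT	2	11.2
Heart	Ndufs7	MUT	3	>19.5
Heart	Wrap73	WT	1	8.5
Heart	Wrap73	WT	2	>7.9
Heart	Wrap73	WT	3	>7.7
Heart	Wrap73	MUT	1	3.6
Heart	Wrap73	MUT	2	3.7
Heart	Wrap73	MUT	3	2.3
Lung	Pick1	WT	1	>6.4
Lung	Pick1	WT	2	>4.1
Lung	Pick1	WT	3	>3.8
Lung	Pick1	MUT	1	3.6
Lung	Pick1	MUT	2	5.4
Lung	Pick1	MUT	3	5.0
Lung	Gas2l1	WT	1	3.6
Lung	Gas2l1	WT	2	>7.1
Lung	Gas2l1	WT	3	>6.7
Lung	Gas2l1	MUT	1	-0.9
Lung	Gas2l1	MUT	2	1.0
Lung	Gas2l1	MUT	3	-0.3
Lung	Osbpl2	WT	1	4.4
Lung	Osbpl2	WT	2	6.3
Lung	Osbpl2	WT	3	>3.6
Lung	Osbpl2	MUT	1	-1.0
Lung	Osbpl2	MUT	2	2.3
Lung	Osbpl2	MUT	3	ND
Lung	Ndufs7	WT	1	13.8
Lung	Ndufs7	WT	2	>17.4
Lung	Ndufs7	WT	3	>14.8
Lung	Ndufs7	MUT	1	8.7
Lung	Ndufs7	MUT	2	10.3
Lung	Ndufs7	MUT	3	>10
Lung	Wrap73	WT	1	8.1
Lung	Wrap73	WT	2	7.3
Lung	Wrap73	WT	3	>10.5
Lung	Wrap73	MUT	1	1.9
Lung	Wrap73	MUT	2	2.1
Lung	Wrap73	MUT	3	3.9
Duodenum	Pick1	WT	1	>6.0
Duodenum	Pick1	WT	2	8.3
Duodenum	Pick1	WT	3	ND
Duodenum	Pick1	MUT	1	3.0
Duodenum	Pick1	MUT	2	ND
Duodenum	Pick1	MUT	3	1.1
Duodenum	Gas2l1	WT	1	6.2
Duodenum	Gas2l1	WT	2	5.6
Duodenum	Gas2l1	WT	3	>3.9
Duodenum	Gas2l1	MUT	1	7.0
Duodenum	Gas2l1	MUT	2	-0.4
Duodenum	Gas2l1	MUT	3	1.7
Duodenum	Osbpl2	WT	1	2
Duodenum	Osbpl2	WT	2	4.4
Duodenum	Osbpl2	WT	3	2.0
Duodenum	Osbpl2	MUT	1	-1.1
Duodenum	Osbpl2	MUT	2	-1.2
Duodenum	Osbpl2	MUT	3	-0.6
Duodenum	Ndufs7	WT	1	>11.8
Duodenum	Ndufs7	WT	2	>18.6
Duodenum	Ndufs7	WT	3	>16.2
Duodenum	Ndufs7	MUT	1	>9.7
Duodenum	Ndufs7	MUT	2	9.1
Duodenum	Ndufs7	MUT	3	11.3
Duodenum	Wrap73	WT	1	8.2
Duodenum	Wrap73	WT	2	6.4
Duodenum	Wrap73	WT	3	>10.0
Duodenum	Wrap73	MUT	1	4.0
Duodenum	Wrap73	MUT	2	1.5
Duodenum	Wrap73	MUT	3	1.1
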