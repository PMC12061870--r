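drug	block	level	n
adalimumab	total	Reports	594416
golimumab	total	Reports	43845
certolizumab pegol	total	Reports	72344
etanercept	total	Reports	502466
infliximab	total	Reports	169556
ALL	total	Reports	1382627
adalimumab	sex	Female	381842
golimumab	sex	Female	28518
certolizumab pegol	sex	Female	53737
etanercept	sex	Female	346138
infliximab	sex	Female	75769
ALL	sex	Female	886004
adalimumab	sex	Male	188102
golimumab	sex	Male	11855
certolizumab pegol	sex	Male	16032
etanercept	sex	Male	123053
infliximab	sex	Male	52758
ALL	sex	Male	391800
adalimumab	sex	Missing	24472
golimumab	sex	Missing	3472
certolizumab pegol	sex	Missing	2575
etanercept	sex	Missing	33275
infliximab	sex	Missing	41029
ALL	sex	Missing	104823
adalimumab	age	<18	10016
golimumab	age	<18	265
certolizumab pegol	age	<18	774
etanercept	age	<18	10378
infliximab	age	<18	12265
ALL	age	<18	33698
adalimumab	age	18-65	307723
golimumab	age	18-65	26508
certolizumab pegol	age	18-65	36570
etanercept	age	18-65	333204
infliximab	age	18-65	75844
ALL	age	18-65	779849
adalimumab	age	>65	2015
golimumab	age	>65	283
certolizumab pegol	age	>65	227
etanercept	age	>65	2509
infliximab	age	>65	395
ALL	age	>65	5429
adalimumab	age	Missing	274662
golimumab	age	Missing	16789
certolizumab pegol	age	Missing	34773
etanercept	age	Missing	156375
infliximab	age	Missing	81052
ALL	age	Missing	563651
adalimumab	occupation	Consumer	433292
golimumab	occupation	Consumer	19145
certolizumab pegol	occupation	Consumer	31039
etanercept	occupation	Consumer	190460
infliximab	occupation	Consumer	39786
ALL	occupation	Consumer	713722
adalimumab	occupation	Health professional	20610
golimumab	occupation	Health professional	5902
certolizumab pegol	occupation	Health professional	12625
etanercept	occupation	Health professional	10051
infliximab	occupation	Health professional	37302
ALL	occupation	Health professional	86490
adalimumab	occupation	Lawyer	129
golimumab	occupation	Lawyer	6
certolizumab pegol	occupation	Lawyer	19
etanercept	occupation	Lawyer	56
infliximab	occupation	Lawyer	95
ALL	occupation	Lawyer	305
adalimumab	occupation	Physician	67040
golimumab	occupation	Physician	8007
certolizumab pegol	occupation	Physician	11608
etanercept	occupation	Physician	221185
infliximab	occupation	Physician	50827
ALL	occupation	Physician	358667
adalimumab	occupation	Other health-professional	24368
golimumab	occupation	Other health-professional	5932
certolizumab pegol	occupation	Other health-professional	9920
etanercept	occupation	Other health-professional	56024
infliximab	occupation	Other health-professional	35272
ALL	occupation	Other health-professional	131516
adalimumab	occupation	Pharmacist	11885
golimumab	occupation	Pharmacist	4206
certolizumab pegol	occupation	Pharmacist	5970
etanercept	occupation	Pharmacist	13448
infliximab	occupation	Pharmacist	5079
ALL	occupation	Pharmacist	40588
adalimumab	occupation	Registered nurse	80
golimumab	occupation	Registered nurse	4
certolizumab pegol	occupation	Registered nurse	64
etanercept	occupation	Registered nurse	58
infliximab	occupation	Registered nurse	26
ALL	occupation	Registered nurse	232
adalimumab	occupation	Missing	37012
golimumab	occupation	Missing	643
certolizumab pegol	occupation	Missing	1099
etanercept	occupation	Missing	11184
infliximab	occupation	Missing	1169
ALL	occupation	Missing	51107
adalimumab	thrombosis	Reports	5323
golimumab	thrombosis	Reports	277
ALL	thrombosis	Reports	9714
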