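kind,item,group,n
count,total,all,21774
count,sex,male,12556
count,sex,female,9218
count,age_group,0-4,2604
count,age_group,5-9,4688
count,age_group,10-14,5726
count,age_group,15-19,3592
count,age_group,20-24,2494
count,age_group,25-30,2670
count,under18,yes,15426
count,nativity,native,16590
count,nativity,non_native,5178
rate,incidence_2005_2010,,35.6
rate,incidence_2016_2022,,36.6
rate,incidence_overall,,36.0
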