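"plan_id","startup_rule","startup_n","monitor_rule","monitor_n"
1,"1_2.5s",1,"1_3s",1
2,"1_3s",2,"1_3s",1
3,"1_2s",1,"1_3s",1
4,"MR",4,"1_3s",2
5,"1_3s",4,"1_2.5s",1
6,"MR",4,"1_3s",4
7,"1_3s",4,"1_3s",1
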