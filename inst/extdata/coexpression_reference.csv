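region,marker,sex,n,mean_count,mean_count_sem,pct_coexpress,pct_sem
CA1,PV,female,5,28,3,53,10
CA1,PV,male,4,23,4,50,6
CA1,PV,all,9,26,3,52,6
CA3,PV,female,5,19,2,45,8
CA3,PV,male,4,22,3,40,5
CA3,PV,all,9,20,2,43,5
DG,PV,female,5,4,1,70,14
DG,PV,male,4,8,1,65,10
DG,PV,all,9,6,1,68,9
ACC,PV,female,4,65,22,43,9
ACC,PV,male,2,51,17,43,9
ACC,PV,all,6,60,14,43,7
PL,PV,female,4,43,14,34,10
PL,PV,male,2,37,9,29,4
PL,PV,all,6,41,8,32,6
IL,PV,female,4,37,11,43,14
IL,PV,male,2,46,12,42,8
IL,PV,all,6,40,8,43,8
CA1,SST,female,2,14,6,25,14
CA1,SST,male,3,16,3,10,7
CA1,SST,all,5,15,3,16,7
CA3,SST,female,2,14,9,21,15
CA3,SST,male,3,7,2,16,11
CA3,SST,all,5,10,4,18,9
DG,SST,female,2,14,9,8,9
DG,SST,male,3,4,1,4,6
DG,SST,all,5,8,4,6,5
ACC,SST,female,3,37,9,7,5
ACC,SST,male,3,29,6,4,3
ACC,SST,all,6,33,5,6,3
PL,SST,female,3,18,5,10,7
PL,SST,male,3,17,6,4,4
PL,SST,all,6,18,4,7,4
IL,SST,female,3,18,7,18,10
IL,SST,male,3,17,3,6,3
IL,SST,all,6,17,4,12,6
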