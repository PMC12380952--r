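task,model,mean_s1,std_s1,mean_s2,std_s2,t,dof,cohen_d
LDT,M1,0.2242,0.2151,0.1215,0.2011,5.6254,103,0.4933
LDT,M2,0.0597,0.2226,-0.0196,0.209,4.7955,103,0.3673
RMT,M1,0.1992,0.2209,0.1202,0.2301,3.4997,102,0.3502
RMT,M2,0.3969,0.2121,0.1665,0.1634,9.7216,102,1.2169
APT,M1,0.1866,0.2274,0.2124,0.214,-1.6192,127,0.1167
APT,M2,0.0972,0.2311,0.0793,0.2248,1.1328,127,0.0782
ELP,M1,0.2491,0.2816,0.2067,0.2677,5.0196,805,0.1543
ELP,M2,-0.1624,0.269,-0.156,0.2734,-0.8376,805,0.0236
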