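group,mean,sd,n
size_change,19.1,11.6,6
stable,16.8,5.6,5
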