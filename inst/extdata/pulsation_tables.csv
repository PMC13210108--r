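table,exposure,a,b,c,d
swp_vs_size_change,spatial wall pulsation,6,3,0,2
gvp_vs_size_change,global volumetric pulsation,4,4,2,1
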