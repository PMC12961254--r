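polyploid,truth_class,category,n_regions
polyA,additive,additive,16
polyA,additive,dominant_maternal,5
polyA,additive,dominant_paternal,4
polyA,dominant_maternal,dominant_maternal,23
polyA,dominant_paternal,additive,1
polyA,dominant_paternal,dominant_paternal,27
polyA,dominant_paternal,transgressive_up,1
polyA,null,dominant_maternal,1
polyA,null,dominant_paternal,1
polyA,null,no_change,80
polyA,null,transgressive_down,1
polyA,transgressive_down,transgressive_down,18
polyA,transgressive_up,transgressive_up,22
polyB,additive,additive,20
polyB,additive,dominant_maternal,3
polyB,additive,dominant_paternal,2
polyB,dominant_maternal,dominant_maternal,23
polyB,dominant_paternal,additive,1
polyB,dominant_paternal,dominant_paternal,28
polyB,null,dominant_paternal,2
polyB,null,no_change,80
polyB,null,transgressive_down,1
polyB,transgressive_down,transgressive_down,18
polyB,transgressive_up,transgressive_up,22
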