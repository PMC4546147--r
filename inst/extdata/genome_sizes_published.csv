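phage,genome_bp,gc_percent,trna,subgroup
CP21,182761,27.2,Thr/Pro,CP21_subgroup
CP220,177493,27.4,Arg/Tyr,CP220_subgroup
CPt10,175720,27.3,Arg/Tyr,CP220_subgroup
IBB_35,172065,27.4,Arg/Tyr,CP220_subgroup
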