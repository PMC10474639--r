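# ccwmsm 0.1.0 seed=7
day,odds_ratio,ci_lower,ci_upper,n_bootstrap,n_failed,seed
30,1.10059829775404,0.68276212169381,1.98263473746621,20,0,7
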