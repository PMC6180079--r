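 &FCI NORB=2,NELEC=2,MS2=0,
 &END
0.6746 1 1 1 1
0.6635 1 1 2 2
0.6975 2 2 2 2
0.1813 1 2 1 2
-1.2525 1 1 0 0
-0.4759 2 2 0 0
0.7137 0 0 0 0
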