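year,verhulst,regression
2012,52130,62402
2013,47911,73962
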