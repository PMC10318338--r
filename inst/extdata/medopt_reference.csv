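alternative,unweighted_total,unweighted_rank,weighted_total,weighted_rank
Computerised Interface,25,First,83.8,First
Built Environment,24,Second,79.6,Second
Written Communication,22,Joint third,71.6,Third
Face-to-Face,22,Joint third,67.8,Fourth
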