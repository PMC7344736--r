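from_state,to_state,count
stable,stable,58
stable,recurrence,3
stable,metastasis,9
stable,death,8
recurrence,stable,3
recurrence,recurrence,0
recurrence,metastasis,0
recurrence,death,0
metastasis,stable,9
metastasis,recurrence,0
metastasis,metastasis,0
metastasis,death,0
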