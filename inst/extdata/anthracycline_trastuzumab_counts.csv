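from_state,to_state,count
stable,stable,98
stable,recurrence,4
stable,metastasis,4
stable,death,0
recurrence,stable,3
recurrence,recurrence,0
recurrence,metastasis,1
recurrence,death,0
metastasis,stable,3
metastasis,recurrence,0
metastasis,metastasis,1
metastasis,death,0
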