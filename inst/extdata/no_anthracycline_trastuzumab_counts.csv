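from_state,to_state,count
stable,stable,37
stable,recurrence,1
stable,metastasis,1
stable,death,0
recurrence,stable,1
recurrence,recurrence,0
recurrence,metastasis,0
recurrence,death,0
metastasis,stable,0
metastasis,recurrence,0
metastasis,metastasis,2
metastasis,death,0
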