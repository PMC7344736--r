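from_state,to_state,count
stable,stable,400
stable,recurrence,6
stable,metastasis,16
stable,death,1
recurrence,stable,5
recurrence,recurrence,1
recurrence,metastasis,1
recurrence,death,0
metastasis,stable,8
metastasis,recurrence,0
metastasis,metastasis,5
metastasis,death,1
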