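trial_id,n_control,events_control,n_treated,events_treated,followup_years
synthetic01,1000,391,1000,271,1
synthetic02,200,59,200,43,1
synthetic03,500,112,500,81,1
synthetic04,500,39,500,39,1
synthetic05,1000,194,1000,158,1
synthetic06,500,62,500,72,1
synthetic07,1000,294,1000,225,1
synthetic08,1000,137,1000,113,1
synthetic09,500,176,500,130,1
synthetic10,500,79,500,89,1
synthetic11,1000,189,1000,153,1
synthetic12,1000,327,1000,247,1
synthetic13,200,71,200,47,1
synthetic14,500,102,500,82,1
synthetic15,200,49,200,51,1
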