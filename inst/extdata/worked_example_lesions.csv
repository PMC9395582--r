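patient_id,dominance,segment,stenosis_pct,composition
case_example,right,Left main,30,mixed
case_example,right,LAD proximal,30,mixed
case_example,right,LAD mid,30,mixed
case_example,right,1st diagonal,30,calcified
case_example,right,LCx proximal,30,calcified
case_example,right,RCA proximal,30,calcified
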