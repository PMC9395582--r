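block,category,control,low,moderate,high
segment,RCA proximal,18,22,32,34
segment,RCA mid,17,14,24,26
segment,RCA distal,13,8,17,14
segment,PDA,3,3,9,7
segment,Left main,12,8,18,24
segment,LAD proximal,37,32,38,48
segment,LAD mid,25,15,22,27
segment,LAD distal,1,0,2,2
segment,1st diagonal,7,8,18,21
segment,2nd diagonal,1,0,6,3
segment,LCx proximal,16,15,27,26
segment,1st obtuse marginal,5,3,9,13
segment,LCx distal,3,2,5,6
segment,2nd obtuse marginal,0,0,2,2
segment,PDA from LCA,0,0,0,0
segment,PL branch from LCA,0,2,5,5
segment,PL branch from RCA,1,0,1,4
segment,Intermediate branch,0,0,0,0
severity,Obstructive stenosis,21,29,107,124
severity,Non-obstructive stenosis,138,103,128,138
composition,Non-calcified or mixed,139,128,214,234
composition,Calcified,20,4,21,28
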