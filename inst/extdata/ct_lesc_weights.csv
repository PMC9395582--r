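segment,dominance,weight
rca_proximal,right,1
rca_proximal,left,0
rca_proximal,balanced,0.5
rca_mid,right,1
rca_mid,left,0
rca_mid,balanced,0.5
rca_distal,right,1
rca_distal,left,0
rca_distal,balanced,0.5
pda,right,1
pda,left,na
pda,balanced,0.5
left_main,right,5
left_main,left,6
left_main,balanced,5.5
lad_proximal,right,3.5
lad_proximal,left,3.5
lad_proximal,balanced,3.5
lad_mid,right,2.5
lad_mid,left,2.5
lad_mid,balanced,2.5
lad_distal,right,1
lad_distal,left,1
lad_distal,balanced,1
diagonal_1,right,1
diagonal_1,left,1
diagonal_1,balanced,1
diagonal_2,right,0.5
diagonal_2,left,0.5
diagonal_2,balanced,0.5
lcx_proximal,right,1.5
lcx_proximal,left,2.5
lcx_proximal,balanced,2
obtuse_marginal_1,right,1
obtuse_marginal_1,left,1
obtuse_marginal_1,balanced,1
lcx_distal,right,0.5
lcx_distal,left,1.5
lcx_distal,balanced,1
obtuse_marginal_2,right,1
obtuse_marginal_2,left,1
obtuse_marginal_2,balanced,1
pda_from_lca,right,na
pda_from_lca,left,1
pda_from_lca,balanced,na
pl_branch_from_lca,right,na
pl_branch_from_lca,left,0.5
pl_branch_from_lca,balanced,0.5
pl_branch_from_rca,right,0.5
pl_branch_from_rca,left,na
pl_branch_from_rca,balanced,na
intermediate_branch,right,1
intermediate_branch,left,1
intermediate_branch,balanced,1
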