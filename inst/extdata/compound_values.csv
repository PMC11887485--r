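analyte_id,common_name,normalized_dff,normalized_sd,category,has_vicinal_donors,conjugated,net_charge,note
DA,dopamine,1.00,NA,I,TRUE,TRUE,1,plate reference; normalized to 1.00 by definition
T,catechol,0.208,0.032,III,TRUE,TRUE,0,ortho-dihydroxybenzene
1,resorcinol,-0.056,0.025,IV,FALSE,TRUE,0,meta-dihydroxybenzene; donors not vicinal
MM,pyrogallol,NA,NA,NA,TRUE,TRUE,0,positive control; response value not printed
OO,octopamine,NA,NA,NA,FALSE,TRUE,1,negative control; single ring hydroxy
RR,NA,NA,NA,NA,TRUE,TRUE,0,noncatechol tolerated by the donor/conjugation rule
O,NA,NA,NA,NA,TRUE,TRUE,0,noncatechol tolerated by the donor/conjugation rule
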