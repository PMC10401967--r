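gene_label	family	skip_saltbridge	skip_actloopct
OTHER_WNK1	OTHER	TRUE	FALSE
OTHER_WNK2	OTHER	TRUE	FALSE
OTHER_WNK3	OTHER	TRUE	FALSE
OTHER_WNK4	OTHER	TRUE	FALSE
TKL_MAP3K12	TKL	TRUE	FALSE
TKL_MAP3K13	TKL	TRUE	FALSE
OTHER_HASPIN	OTHER	FALSE	TRUE
OTHER_TP53RK	OTHER	FALSE	TRUE
OTHER_PKDCC	OTHER	FALSE	TRUE
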