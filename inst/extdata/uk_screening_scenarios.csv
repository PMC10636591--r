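scenario,label,n_contacted,followup_cost_per_patient,n_followup,n_referred,n_cases
1,conventional model,106738,0,22109,22109,819
2,conventional + FEV1 + alcohol + waist,106738,63.42,22109,18930,765
3,conventional + liver blood tests + urate,106738,7.16,22109,18599,757
4,fully expanded,106738,70.58,22109,17468,753
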