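scenario,dose_mg_eq,cmax_ng_ml,auc0t_ng_h_ml,tmax_h,source
arl_im_150,150,40.66,52810,1081.9,published clinical PK summary; aripiprazole lauroxil IM suspension
arl_im_300,300,87.61,91910,1058.2,published clinical PK summary; aripiprazole lauroxil IM suspension
arl_im_400,400,97.39,138100,723.26,published clinical PK summary; aripiprazole lauroxil IM suspension
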