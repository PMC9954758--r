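outcome,predictor,estimate,se,t_printed,df,prior_lower,prior_upper
reading_accuracy,iq,-0.611,0.277,-2.21,51,-0.57,0
reading_accuracy,memory,-1.068,0.58,-1.84,51,-0.82,0
reading_accuracy,ran_speed,-0.277,0.199,-1.388,51,-0.70,0
reading_accuracy,visual_search_speed,-0.0832,0.239,-0.349,51,-0.89,0
reading_accuracy,phon_awareness,-0.13,0.127,-1.025,51,-0.58,0
reading_speed,iq,-0.293,0.238,-1.231,51,-0.68,0
reading_speed,memory,-0.457,0.49,-0.931,51,-0.78,0
reading_speed,ran_speed,-0.706,0.332,-2.13,51,-0.97,0
reading_speed,visual_search_speed,-0.5298,0.184,-2.882,51,-0.93,0
reading_speed,phon_awareness,-0.227,0.116,-1.965,51,-0.50,0
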