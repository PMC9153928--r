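modality,condition,stratum,n,parameter,mean
auditory_verbal,silence,total,31,H,0.887
auditory_verbal,silence,total,31,F,0.110
auditory_verbal,pure_tone_240Hz,total,31,H,0.877
auditory_verbal,pure_tone_240Hz,total,31,F,0.118
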