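feature,coef,min,max,type,position
intercept,-1.2926,,,,
threshold,0.5243,,,,
age,0.0322,0,100,continuous,up
gender,-0.0696,0,1,nominal,up
underlying_disease,0.5492,0,1,nominal,up
prednisone_dose,0.0963,0,50,continuous,up
cd34_count,-0.0771,0,20,continuous,up
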