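muscle,parameter,cv,n_subjects,source
vaslat,MIF,0.22,20,squatmc-default
vasmed,MIF,0.2,20,squatmc-default
vasint,MIF,0.21,20,squatmc-default
recfem,MIF,0.18,20,squatmc-default
bflh,MIF,0.2,20,squatmc-default
bfsh,MIF,0.25,20,squatmc-default
semimem,MIF,0.22,20,squatmc-default
semiten,MIF,0.24,20,squatmc-default
gasmed,MIF,0.18,20,squatmc-default
gaslat,MIF,0.2,20,squatmc-default
soleus,MIF,0.16,20,squatmc-default
tibant,MIF,0.18,20,squatmc-default
glmax,MIF,0.2,20,squatmc-default
vaslat,TSL,0.05,20,squatmc-default
vasmed,TSL,0.05,20,squatmc-default
vasint,TSL,0.05,20,squatmc-default
recfem,TSL,0.04,20,squatmc-default
bflh,TSL,0.06,20,squatmc-default
bfsh,TSL,0.07,20,squatmc-default
semimem,TSL,0.05,20,squatmc-default
semiten,TSL,0.06,20,squatmc-default
gasmed,TSL,0.03,20,squatmc-default
gaslat,TSL,0.03,20,squatmc-default
tibant,TSL,0.04,20,squatmc-default
glmax,TSL,0.08,20,squatmc-default
iliopsoas,TSL,0.09,20,squatmc-default
vaslat,PEN,0.12,20,squatmc-default
vasmed,PEN,0.12,20,squatmc-default
vasint,PEN,0.12,20,squatmc-default
recfem,PEN,0.1,20,squatmc-default
bflh,PEN,0.12,20,squatmc-default
bfsh,PEN,0.15,20,squatmc-default
semimem,PEN,0.12,20,squatmc-default
semiten,PEN,0.14,20,squatmc-default
gasmed,PEN,0.1,20,squatmc-default
gaslat,PEN,0.1,20,squatmc-default
soleus,PEN,0.12,20,squatmc-default
iliopsoas,PEN,0.12,20,squatmc-default
glmax,PEN,0.1,20,squatmc-default
vaslat,MIF,0.28,10,squatmc-default-b
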