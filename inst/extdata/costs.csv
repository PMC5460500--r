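item,stage,value
colonoscopy,NA,750
polypectomy,NA,250
sigmoidoscopy,NA,250
fobt,NA,20
major_bleed,NA,4000
minor_bleed,NA,300
mucosal_burn,NA,3000
perforation,NA,15000
treat_initial,1,32000
treat_initial,2,45000
treat_initial,3,55000
treat_initial,4,65000
treat_continuing,1,2000
treat_continuing,2,2500
treat_continuing,3,3500
treat_continuing,4,8000
treat_terminal,1,52000
treat_terminal,2,55000
treat_terminal,3,60000
treat_terminal,4,70000
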