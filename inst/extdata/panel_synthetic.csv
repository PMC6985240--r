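# synthetic fixture panel: drug names only; concentrations are placeholders
drug,unit,c0,c1,c2
bortezomib,uM,0,0.01,0.1
panobinostat,uM,0,0.001,0.01
pralatrexate,uM,0,10,100
cisplatin,uM,0,1,10
cytarabine,uM,0,0.5,5
l-asparaginase,uM,0,0.1,1
gemcitabine,uM,0,0.05,0.5
dexamethasone,uM,0,0.1,1
methotrexate,uM,0,0.05,0.5
etoposide,uM,0,0.5,5
ifosfamide,uM,0,5,50
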