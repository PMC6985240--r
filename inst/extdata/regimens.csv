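regimen,drug
SMILE,dexamethasone
SMILE,methotrexate
SMILE,ifosfamide
SMILE,l-asparaginase
SMILE,etoposide
GDP,gemcitabine
GDP,dexamethasone
GDP,cisplatin
BP,bortezomib
BP,panobinostat
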