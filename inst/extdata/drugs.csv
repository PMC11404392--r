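drug_code,drug_name,opioid_class,strength_mg_per_unit,mme_factor
MOR15,morphine sulfate IR 15 mg tablet,analgesic,15,1
MOR30,morphine sulfate IR 30 mg tablet,analgesic,30,1
OXY5,oxycodone 5 mg tablet,analgesic,5,1.5
OXY10,oxycodone 10 mg tablet,analgesic,10,1.5
OXY30,oxycodone 30 mg tablet,analgesic,30,1.5
HYD5,hydrocodone-acetaminophen 5-325 mg tablet,combination,5,1
HYD10,hydrocodone-acetaminophen 10-325 mg tablet,combination,10,1
HM2,hydromorphone 2 mg tablet,analgesic,2,4
HM4,hydromorphone 4 mg tablet,analgesic,4,4
TRA50,tramadol 50 mg tablet,analgesic,50,0.1
COD30,codeine-acetaminophen 30-300 mg tablet,combination,30,0.15
TAP50,tapentadol 50 mg tablet,analgesic,50,0.4
OXM5,oxymorphone 5 mg tablet,analgesic,5,3
GFC10,guaifenesin-codeine 100-10 mg/5 mL syrup,antitussive,10,0.15
HCH5,hydrocodone-homatropine 5-1.5 mg tablet,antitussive,5,1
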