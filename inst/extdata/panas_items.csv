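item,label,subscale
na1,Upset,NA
na2,Hostile,NA
na3,Ashamed,NA
na4,Nervous,NA
na5,Afraid,NA
pa1,Active,PA
pa2,Determined,PA
pa3,Attentive,PA
pa4,Inspired,PA
pa5,Alert,PA
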