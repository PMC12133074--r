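code,description
W01,Question of pregnancy
W03,Antepartum bleeding
W05,Vomiting or nausea of pregnancy
W17,Postpartum bleeding
W18,Postpartum symptom or complaint
W19,Breast or lactation symptom
W21,Concern about body image in pregnancy
W27,Fear of complications of pregnancy
W28,Limited function or disability in pregnancy
W29,Other symptom or complaint of pregnancy
W70,Puerperal infection or sepsis
W71,Infection complicating pregnancy
W75,Injury complicating pregnancy
W76,Congenital anomaly complicating pregnancy
W78,Pregnancy confirmed
W79,Unwanted pregnancy confirmed
W80,Ectopic pregnancy
W81,Toxaemia of pregnancy
W82,Abortion spontaneous
W83,Abortion induced
W84,Pregnancy high risk
W92,Complicated delivery liveborn
W96,Other complication of puerperium
W99,Other disorder of pregnancy or delivery
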