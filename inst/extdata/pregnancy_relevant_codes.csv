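code,description,category
W78,Pregnancy confirmed,pregnancy_related
U71,Cystitis or other urine infection,general
W05,Vomiting or nausea of pregnancy,pregnancy_related
W82,Abortion spontaneous,pregnancy_related
W79,Unwanted pregnancy confirmed,pregnancy_related
U02,Frequent or urgent urination,general
X72,Urogenital candidiasis,general
W84.02,Gestational diabetes mellitus,pregnancy_related
D06,Other localized abdominal pain,general
D12,Constipation,general
W03,Antepartum bleeding,pregnancy_related
W29,Other symptom or complaint of pregnancy,pregnancy_related
P76,Depressive disorder,general
R74,Upper respiratory infection acute,general
L03,Low back symptom or complaint,general
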