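patient_id,age,gender,ecg,bp,label
ID001,34,Male,223,130,
ID002,41,Female,190,90,
ID003,29,Male,67,110,
ID004,59,Female,90,110,
ID005,22,Female,91,89,
ID006,24,Male,100,80,
ID007,45,Female,129,90,
ID008,30,Male,143,81,
ID009,43,Male,189,120,
ID010,46,Male,190,120,
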