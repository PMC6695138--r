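sample	group
1CAI-a	AA
4CA-a	AA
1CBC-a	AA
1EBA-a	AA
1CAD-f	AA
1CAF-a	AA
1CAC-a	AA
3CC-a	AA
1CAD-a	AA
1CE-a	AA
1EAG-a	AA
1CD-a	AA
1CF-a	AA
1CCB-a	AA
1EB-a	AA
1CAG-a	AA
1CB-a	AA
1CAH-a	AA
1EAH-a	AA
1CBH-a	AA
1CC-a	AA
1EC-a	AA
SYN-AA-01	AA
1ED-a	EA
1CBE-a	EA
1EE-a	EA
1EAD-a	EA
1EAC-a	EA
1EAJ-a	EA
1CG-a	EA
1EA-a	EA
1CAB-a	EA
1EG-a	EA
1CA-a	EA
SYN-EA-01	EA
SYN-EA-02	EA
SYN-EA-03	EA
SYN-EA-04	EA
SYN-EA-05	EA
SYN-EA-06	EA
SYN-EA-07	EA
SYN-EA-08	EA
SYN-EA-09	EA
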