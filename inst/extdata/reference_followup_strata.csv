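"stratum","n","followed","events_6mo"
"screened",3722,3640,38
"detected",115,101,9
"detected_not_referred",,49,3
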