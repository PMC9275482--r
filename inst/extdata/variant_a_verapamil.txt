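# continuous-perfusion protocol (variant A): verapamil at its EC75
total_duration: 22
flow_rate: 300
segment: 0 4 saline 0
segment: 4 13.5 verapamil 3e-5
segment: 13.5 22 saline 0
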