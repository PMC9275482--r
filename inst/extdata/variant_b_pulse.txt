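# pulse-application protocol (variant B): solanine bolus during verapamil
total_duration: 22
flow_rate: 300
segment: 0 4 saline 0
segment: 4 13.5 verapamil 3e-5
segment: 13.5 22 saline 0
pulse: 8 solanine 1e-5 0.1
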