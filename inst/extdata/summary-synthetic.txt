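Data Sampling Rate: 256 Hz
(synthetic example of the CHB-MIT summary listing format)

File Name: rec01.edf
Number of Seizures in File: 2
Seizure 1 Start Time: 2996 seconds
Seizure 1 End Time: 3036 seconds
Seizure 2 Start Time: 8721 seconds
Seizure 2 End Time: 8759 seconds

File Name: rec02.edf
Number of Seizures in File: 1
Seizure Start Time: 1467 seconds
Seizure End Time: 1494 seconds
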