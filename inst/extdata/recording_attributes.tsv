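name	source
SamplingRate	NIX
sampling_rate	EEGBase
NumberOfChannels	EEGBase
nr_of_signals	EDF+
ChannelResolution	EEGBase
Dimensions	NIX
Source	NIX
Tags	NIX
DataFormat	EEGBase
recording_id	EEGBase
file_uuid	NIX
startdate_of_recording	EDF+
RecordingStart	NIX
PatientID	EDF+
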