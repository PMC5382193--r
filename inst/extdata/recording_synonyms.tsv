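name	semantic_key
SamplingRate	sampling-rate
sampling_rate	sampling-rate
NumberOfChannels	channel-count
nr_of_signals	channel-count
startdate_of_recording	recording-start
RecordingStart	recording-start
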