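branch	name	dtype	definition
data_array	Dimensions	text	Dimension descriptors of the stored data array (sampled, range or set dimensions)
data_array	Source	text	Data source the array derives from, typically the channel specification
data_array	Tags	text	Tags annotating specific parts of the data, e.g. time points or intervals
data_array	DataFile	binary	Binary raw-waveform payload, e.g. a BrainVision .eeg file
data_array	DataFormat	string	Binary or ASCII representation of the stored samples
data_array	SamplingInterval	float	Sampling interval of the recording in microseconds
data_array	NumberOfChannels	int	Number of recorded channels
data_array	ChannelResolution	float	Per-channel resolution applied to raw samples
results	StimuliCount	int	Number of stimuli presented during the experiment
results	ArtifactCount	int	Number of epochs rejected as artifacts
results	AverageReactionTime	float	Mean reaction time across valid trials, in milliseconds
results	ResultSummary	text	Free-text summary of the recording results
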