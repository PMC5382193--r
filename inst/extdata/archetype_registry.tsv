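name	rm	status	source
Report	Composition	ckm_reused	manifest
Medication order	Instruction	ckm_reused	manifest
Problem/Diagnosis	Evaluation	ckm_reused	manifest
Device	Cluster	ckm_reused	manifest
Device details	Cluster	extended	manifest
Environmental conditions	Cluster	ckm_reused	manifest
Person	Cluster	ckm_reused	manifest
EEG/ERP result	Observation	new	generated
Experiment scenario	Cluster	new	generated
Software	Cluster	new	generated
Stimulus	Cluster	new	generated
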