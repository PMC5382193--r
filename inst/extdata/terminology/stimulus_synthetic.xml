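<?xml version="1.0" encoding="UTF-8"?>
<odML version="1">
  <section>
    <name>Stimulus</name>
    <type>stimulus</type>
    <definition>Synthetic stand-in for the stimulus section of the odML terminology for electrophysiology: properties describing the stimulus presented during an EEG/ERP trial; the type enumeration distinguishes the stimulus families that templates later reduce to.</definition>
    <property>
      <name>Type</name>
      <definition>Family of the presented stimulus.</definition>
      <value>movie<type>string</type></value>
      <value>pulse<type>string</type></value>
      <value>ramp<type>string</type></value>
      <value>tone<type>string</type></value>
      <value>image<type>string</type></value>
    </property>
    <property>
      <name>Modality</name>
      <definition>Sensory modality the stimulus addresses.</definition>
      <value>visual<type>string</type></value>
      <value>auditory<type>string</type></value>
      <value>somatosensory<type>string</type></value>
    </property>
    <property>
      <name>Duration</name>
      <definition>Presentation duration of one stimulus.</definition>
      <value>200<type>float</type><unit>ms</unit></value>
    </property>
    <property>
      <name>Amplitude</name>
      <definition>Stimulus amplitude or intensity.</definition>
      <value>0<type>float</type></value>
    </property>
    <property>
      <name>InterStimulusInterval</name>
      <definition>Interval between consecutive stimulus onsets.</definition>
      <value>1000<type>float</type><unit>ms</unit></value>
    </property>
    <property>
      <name>Description</name>
      <definition>Free-text description of the stimulus.</definition>
      <value>unspecified<type>text</type></value>
    </property>
  </section>
</odML>
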