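<?xml version="1.0" encoding="UTF-8"?>
<odML version="1">
  <section>
    <name>Electrode</name>
    <type>hardware</type>
    <definition>Synthetic stand-in for the electrode section of the odML terminology for electrophysiology; reproduces the Electrode/Usage/Reference structure used by the terminology referencing worked example.</definition>
    <property>
      <name>Usage</name>
      <definition>How the electrode was used during the recording.</definition>
      <value>Reference<type>string</type></value>
      <value>Recording<type>string</type></value>
      <value>Ground<type>string</type></value>
    </property>
    <property>
      <name>Impedance</name>
      <definition>Electrode impedance at recording start.</definition>
      <value>5.2<type>float</type><unit>kOhm</unit></value>
    </property>
    <property>
      <name>Material</name>
      <value>Ag/AgCl<type>string</type></value>
    </property>
  </section>
</odML>
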