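<?xml version="1.0" encoding="UTF-8"?>
<odML version="1">
  <section>
    <name>Software</name>
    <type>software</type>
    <definition>Synthetic stand-in for the software section of the odML terminology for electrophysiology: basic information about software used for stimulus presentation, recording or analysis.</definition>
    <property>
      <name>Name</name>
      <definition>Name of the software package.</definition>
      <value>unspecified<type>string</type></value>
    </property>
    <property>
      <name>Owner</name>
      <definition>Producer or owner of the software.</definition>
      <value>unspecified<type>string</type></value>
    </property>
    <property>
      <name>Version</name>
      <definition>Version of the software release.</definition>
      <value>unspecified<type>string</type></value>
    </property>
    <property>
      <name>License</name>
      <definition>License category under which the software is distributed.</definition>
      <value>open-source<type>string</type></value>
      <value>proprietary<type>string</type></value>
      <value>freeware<type>string</type></value>
    </property>
    <property>
      <name>Description</name>
      <definition>Free-text description of the software and its role.</definition>
      <value>unspecified<type>text</type></value>
    </property>
  </section>
</odML>
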