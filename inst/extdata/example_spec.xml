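<U3DObject>
  <ObjectType>lineset</ObjectType>
  <ObjectName>VCG loop</ObjectName>
  <GeometryID>0</GeometryID>
  <GroupPath>Traces</GroupPath>
  <Color>0.8 0.1 0.1</Color>
  <Opacity>1</Opacity>
  <MetaData><Key>unit</Key><Value>mV</Value></MetaData>
</U3DObject>
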