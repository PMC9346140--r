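name: DSI
aoi:
- SVS
- IP
- ND
- DL
- OW
bandwidth:
  SVS: 0.62
  IP: 0.81
  ND: 0.18
  DL: 0.05
  OW: 0.0
subtasks:
- name: AV
  value: 3
- name: NAV
  value: 2
- name: HAZ
  value: 1
relevance:
  AV:
    SVS: 1.0
    IP: 0.5
    ND: 0.0
    DL: 0.0
    OW: 0.0
  NAV:
    SVS: 0.0
    IP: 1.0
    ND: 1.0
    DL: 1.0
    OW: 0.0
  HAZ:
    SVS: 1.0
    IP: 0.0
    ND: 0.5
    DL: 0.0
    OW: 0.0
horizon: 960
period_s: 0.5
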