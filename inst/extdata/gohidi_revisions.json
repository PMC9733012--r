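{
  "name": "expert-interview revision log",
  "note": "Placement of deleted third-level codes within the initial framework is a documented reconstruction: the published log names the codes but not their parent groups.",
  "ops": [
    {"kind": "add", "parent": "1.2", "code": "1.2.6", "name": "COVID-19", "level": 3, "category": "none"},
    {"kind": "delete", "target": "1.2.5"},
    {"kind": "delete", "target": "1.4.4"},
    {"kind": "delete", "target": "1.7.1"},
    {"kind": "delete", "target": "1.7.2"},
    {"kind": "delete", "target": "1.7.3"},
    {"kind": "delete", "target": "2.2.3"},
    {"kind": "delete", "target": "2.2.4"},
    {"kind": "delete", "target": "2.2.5"},
    {"kind": "delete", "target": "2.2.6"},
    {"kind": "delete", "target": "2.2.7"},
    {"kind": "delete", "target": "2.2.8"},
    {"kind": "delete", "target": "2.2.9"},
    {"kind": "delete", "target": "2.2.10"},
    {"kind": "delete", "target": "2.4.7"},
    {"kind": "delete", "target": "2.4.8"},
    {"kind": "delete", "target": "2.4.9"},
    {"kind": "delete", "target": "2.5.1"},
    {"kind": "delete", "target": "3.6.4"},
    {"kind": "delete", "target": "3.7.1"},
    {"kind": "merge", "sources": ["3.1", "3.2"], "code": "3.1", "name": "Air Quality and Climate Change"},
    {"kind": "delete", "target": "1.7"},
    {"kind": "delete", "target": "2.5"},
    {"kind": "delete", "target": "3.7"},
    {"kind": "rename", "target": "3.3", "name": "Land Resources"},
    {"kind": "rename", "target": "3.5", "name": "Hazardous Chemicals"},
    {"kind": "rename", "target": "2.3", "name": "Animal Nutritional Status"}
  ]
}
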