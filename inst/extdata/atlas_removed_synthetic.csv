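"name"
"Brain-Stem"
"Left-Cerebellum-White-Matter"
"Right-Cerebellum-White-Matter"
"Left-VentralDC"
"Right-VentralDC"
"Left-Cerebral-White-Matter"
"Right-Cerebral-White-Matter"
"Left-Lateral-Ventricle"
"Right-Lateral-Ventricle"
"Left-Inf-Lat-Vent"
"Right-Inf-Lat-Vent"
"Left-choroid-plexus"
"Right-choroid-plexus"
"Left-vessel"
"Right-vessel"
"3rd-Ventricle"
"4th-Ventricle"
"CSF"
"Optic-Chiasm"
"WM-hypointensities"
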