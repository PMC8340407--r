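"unit_id","level","reference_ffr","index_ffr","ccta_ds_percent"
"V001","vessel",0.876,0.92,55.3
"V002","vessel",0.895,0.884,55.6
"V003","vessel",0.875,0.832,29.2
"V004","vessel",0.858,0.779,25.9
"V005","vessel",0.917,0.832,35.7
"V006","vessel",0.908,0.874,62.1
"V007","vessel",0.855,0.793,50.8
"V008","vessel",0.954,0.943,36.2
"V009","vessel",0.821,0.834,55.5
"V010","vessel",0.955,0.967,19.5
"V011","vessel",0.883,0.96,37.5
"V012","vessel",0.717,0.654,77.7
"V013","vessel",0.567,0.738,81.5
"V014","vessel",0.938,0.881,44.3
"V015","vessel",0.913,0.852,27.9
"V016","vessel",0.732,0.878,76.6
"V017","vessel",0.701,0.736,58.8
"V018","vessel",0.88,0.934,53.2
"V019","vessel",0.909,0.836,66
"V020","vessel",0.872,0.831,12.2
"V021","vessel",0.949,0.824,21.9
"V022","vessel",0.849,0.711,41.7
"V023","vessel",0.817,0.957,86
"V024","vessel",0.549,0.511,95
"V025","vessel",0.689,0.751,62.9
"V026","vessel",0.9,0.889,52.6
"V027","vessel",0.619,0.541,93.5
"V028","vessel",0.962,0.975,19
"V029","vessel",0.938,0.92,51.4
"V030","vessel",0.575,0.568,74.9
"V031","vessel",0.824,0.856,51.9
"V032","vessel",0.71,0.609,45.9
"V033","vessel",0.924,0.901,56.8
"V034","vessel",0.904,0.879,21.8
"V035","vessel",0.545,0.559,95
"V036","vessel",0.891,0.835,41.4
"V037","vessel",0.856,0.942,50.3
"V038","vessel",0.854,0.901,80.8
"V039","vessel",0.977,0.908,21.7
"V040","vessel",0.834,0.831,68.5
"V041","vessel",0.825,0.927,55.3
"V042","vessel",0.742,0.628,56.9
"V043","vessel",0.896,0.867,23.3
"V044","vessel",0.965,0.861,32.5
"V045","vessel",0.871,0.857,46.2
"V046","vessel",0.903,0.908,30.2
"V047","vessel",0.906,0.893,47.8
"V048","vessel",0.537,0.576,95
"V049","vessel",0.97,0.913,37.5
"V050","vessel",0.778,0.858,49.2
"V051","vessel",0.835,0.904,42.2
"V052","vessel",0.977,0.972,40.9
"V053","vessel",0.553,0.747,87
"V054","vessel",0.917,0.959,50.6
"V055","vessel",0.976,0.836,37.8
"V056","vessel",0.546,0.663,61.2
"V057","vessel",0.889,0.704,35.6
"V058","vessel",0.865,0.824,33.1
"V059","vessel",0.524,0.592,83.4
"V060","vessel",0.851,0.94,30.5
"V061","vessel",0.939,0.848,52.6
"V062","vessel",0.606,0.54,82.6
"V063","vessel",0.864,0.92,47.8
"V064","vessel",0.936,0.949,44.2
"V065","vessel",0.955,0.889,34
"V066","vessel",0.922,0.886,23
"V067","vessel",0.933,0.855,44.3
"V068","vessel",0.825,0.881,33.1
"V069","vessel",0.697,0.704,61
"V070","vessel",0.857,0.773,75.5
"V071","vessel",0.849,0.737,37.4
"V072","vessel",0.718,0.591,84.1
"V073","vessel",0.947,0.892,63.7
"V074","vessel",0.752,0.561,43
"V075","vessel",0.924,0.864,55.9
"V076","vessel",0.767,0.541,69.1
"V077","vessel",0.653,0.683,93.2
"V078","vessel",0.862,0.868,74.7
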