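# nearest-neighbor loop free energies (kcal/mol)
kT 0.61633
theta 3
internal_cap 30
terminal_au 0.5
multi 3.4 0.4 0
hairpin 3 5.4
hairpin 4 5.6
hairpin 5 5.7
hairpin 6 5.4
hairpin 7 6
hairpin 8 5.5
hairpin 9 6.4
bulge 1 3.8
bulge 2 2.8
bulge 3 3.2
bulge 4 3.6
bulge 5 4
bulge 6 4.4
internal 2 1.5
internal 3 1.6
internal 4 1.7
internal 5 1.8
internal 6 2
stack AU AU -1.1
stack UA AU -1.1
stack CG AU -2.2
stack GC AU -2.2
stack GU AU -0.9
stack UG AU -0.9
stack AU UA -1.1
stack UA UA -1.1
stack CG UA -2.2
stack GC UA -2.2
stack GU UA -0.9
stack UG UA -0.9
stack AU CG -2.2
stack UA CG -2.2
stack CG CG -3.3
stack GC CG -3.3
stack GU CG -2
stack UG CG -2
stack AU GC -2.2
stack UA GC -2.2
stack CG GC -3.3
stack GC GC -3.3
stack GU GC -2
stack UG GC -2
stack AU GU -0.9
stack UA GU -0.9
stack CG GU -2
stack GC GU -2
stack GU GU -0.7
stack UG GU -0.7
stack AU UG -0.9
stack UA UG -0.9
stack CG UG -2
stack GC UG -2
stack GU UG -0.7
stack UG UG -0.7
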