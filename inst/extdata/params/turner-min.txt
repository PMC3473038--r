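# turner-min: minimal complete nearest-neighbor parameter set, 37 C.
# Free energies in kcal/mol.  Watson-Crick stack values are the published
# 37 C nearest-neighbor set; GU entries are representative values chosen to
# satisfy the rotational symmetry E[p1,p2] = E[rev(p2),rev(p1)] exactly.
# No tetraloop bonuses, no 1x1/2x2 special internal tables, no dangles,
# no coaxial stacking.
theta 3
temperature 310.15
multiloop_a 3.4
multiloop_b 0.4
multiloop_c 0.0
asymmetry_coef 0.6
asymmetry_max 3.0
max_internal 30
# stack <outer pair i,j> <inner pair i+1,j-1> <dG>
stack AU AU -0.93
stack AU UA -1.10
stack AU GC -2.08
stack AU CG -2.24
stack AU GU -0.55
stack AU UG -1.36
stack UA AU -1.33
stack UA UA -0.93
stack UA GC -2.11
stack UA CG -2.35
stack UA GU -1.00
stack UA UG -1.27
stack CG AU -2.11
stack CG UA -2.08
stack CG GC -2.36
stack CG CG -3.26
stack CG GU -1.41
stack CG UG -2.11
stack GC AU -2.35
stack GC UA -2.24
stack GC GC -3.26
stack GC CG -3.42
stack GC GU -1.53
stack GC UG -2.51
stack GU AU -1.27
stack GU UA -1.36
stack GU GC -2.11
stack GU CG -2.51
stack GU GU -0.50
stack GU UG -0.30
stack UG AU -1.00
stack UG UA -0.55
stack UG GC -1.41
stack UG CG -1.53
stack UG GU 0.47
stack UG UG -0.50
# hairpin <loop length> <dG>  (Jacobson-Stockmayer extrapolation past max)
hairpin 3 5.40
hairpin 4 5.60
hairpin 5 5.70
hairpin 6 5.40
hairpin 7 6.00
hairpin 8 5.50
hairpin 9 6.40
# bulge <size> <dG>
bulge 1 3.80
bulge 2 2.80
bulge 3 3.20
bulge 4 3.60
bulge 5 4.00
bulge 6 4.40
# internal <total size> <dG>
internal 2 1.50
internal 3 1.60
internal 4 1.70
internal 5 1.80
internal 6 2.00
internal 7 2.20
internal 8 2.30
internal 9 2.40
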