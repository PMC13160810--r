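id,name
2,Taking out
3,Local quality
7,Nested doll
10,Preliminary action
12,Equipotentiality
13,The other way round
17,Another dimension
19,Periodic action
25,Self-service
26,Copying
28,Mechanics substitution
31,Porous materials
32,Colour changes
36,Phase transitions
40,Composite materials
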