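# Synthetic reversible single-nucleotide substitution model for unpaired sites.
# GTR with transition/transversion rate ratio 4, A-rich loop equilibrium,
# scaled to one expected substitution per site per unit branch length.
# Constructed for this package (stand-in; not transcribed from a published matrix).
states A C G U
pi             0.33             0.18             0.21             0.28
Q
-0.893839383938394 0.123762376237624 0.577557755775577 0.192519251925193
0.226897689768977 -1.14136413641364 0.144389438943894 0.77007700770077
0.907590759075908 0.123762376237624 -1.22387238723872 0.192519251925193
0.226897689768977 0.495049504950495 0.144389438943894 -0.866336633663366
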