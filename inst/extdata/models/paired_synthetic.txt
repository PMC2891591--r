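# Synthetic reversible dinucleotide substitution model for base-paired sites.
# States AA..UU row-major. Equilibrium mass 0.92 on the six canonical pairs;
# single-position changes rate factor 1, compensatory canonical<->canonical double
# changes 0.25, other double changes 0.02; scaled to one expected event per pair
# per unit branch length.
# Constructed for this package (stand-in; not transcribed from a published matrix).
states AA AC AG AU CA CC CG CU GA GC GG GU UA UC UG UU
pi            0.008            0.008            0.008             0.17            0.008            0.008             0.24            0.008            0.008             0.24            0.008             0.05             0.17            0.008             0.05            0.008
Q
-1.26353334939156 0.0262962195502926 0.0262962195502926 0.558794665443717 0.0262962195502926 0.000525924391005851 0.0157777317301755 0.000525924391005851 0.0262962195502926 0.0157777317301755 0.000525924391005851 0.00328702744378657 0.558794665443717 0.000525924391005851 0.00328702744378657 0.000525924391005851
0.0262962195502926 -1.48902343203532 0.0262962195502926 0.558794665443717 0.000525924391005851 0.0262962195502926 0.0157777317301755 0.000525924391005851 0.000525924391005851 0.788886586508777 0.000525924391005851 0.00328702744378657 0.0111758933088743 0.0262962195502926 0.00328702744378657 0.000525924391005851
0.0262962195502926 0.0262962195502926 -1.62431748162157 0.558794665443717 0.000525924391005851 0.000525924391005851 0.788886586508777 0.000525924391005851 0.000525924391005851 0.0157777317301755 0.0262962195502926 0.00328702744378657 0.0111758933088743 0.000525924391005851 0.164351372189329 0.000525924391005851
0.0262962195502926 0.0262962195502926 0.0262962195502926 -0.873691894558471 0.000525924391005851 0.000525924391005851 0.197221646627194 0.0262962195502926 0.000525924391005851 0.197221646627194 0.000525924391005851 0.164351372189329 0.139698666360929 0.000525924391005851 0.0410878430473321 0.0262962195502926
0.0262962195502926 0.000525924391005851 0.000525924391005851 0.0111758933088743 -1.48902343203532 0.0262962195502926 0.788886586508777 0.0262962195502926 0.0262962195502926 0.0157777317301755 0.000525924391005851 0.00328702744378657 0.558794665443717 0.000525924391005851 0.00328702744378657 0.000525924391005851
0.000525924391005851 0.0262962195502926 0.000525924391005851 0.0111758933088743 0.0262962195502926 -1.71451351467908 0.788886586508777 0.0262962195502926 0.000525924391005851 0.788886586508777 0.000525924391005851 0.00328702744378657 0.0111758933088743 0.0262962195502926 0.00328702744378657 0.000525924391005851
0.000525924391005851 0.000525924391005851 0.0262962195502926 0.139698666360929 0.0262962195502926 0.0262962195502926 -0.816168914292206 0.0262962195502926 0.000525924391005851 0.197221646627194 0.0262962195502926 0.0410878430473321 0.139698666360929 0.000525924391005851 0.164351372189329 0.000525924391005851
0.000525924391005851 0.000525924391005851 0.000525924391005851 0.558794665443717 0.0262962195502926 0.0262962195502926 0.788886586508777 -1.62431748162157 0.000525924391005851 0.0157777317301755 0.000525924391005851 0.164351372189329 0.0111758933088743 0.000525924391005851 0.00328702744378657 0.0262962195502926
0.0262962195502926 0.000525924391005851 0.000525924391005851 0.0111758933088743 0.0262962195502926 0.000525924391005851 0.0157777317301755 0.000525924391005851 -1.62431748162157 0.788886586508777 0.0262962195502926 0.164351372189329 0.558794665443717 0.000525924391005851 0.00328702744378657 0.000525924391005851
0.000525924391005851 0.0262962195502926 0.000525924391005851 0.139698666360929 0.000525924391005851 0.0262962195502926 0.197221646627194 0.000525924391005851 0.0262962195502926 -0.816168914292206 0.0262962195502926 0.164351372189329 0.139698666360929 0.0262962195502926 0.0410878430473321 0.000525924391005851
0.000525924391005851 0.000525924391005851 0.0262962195502926 0.0111758933088743 0.000525924391005851 0.000525924391005851 0.788886586508777 0.000525924391005851 0.0262962195502926 0.788886586508777 -1.98510161385159 0.164351372189329 0.0111758933088743 0.000525924391005851 0.164351372189329 0.000525924391005851
0.000525924391005851 0.000525924391005851 0.000525924391005851 0.558794665443717 0.000525924391005851 0.000525924391005851 0.197221646627194 0.0262962195502926 0.0262962195502926 0.788886586508777 0.0262962195502926 -1.83402983253516 0.139698666360929 0.000525924391005851 0.0410878430473321 0.0262962195502926
0.0262962195502926 0.000525924391005851 0.000525924391005851 0.139698666360929 0.0262962195502926 0.000525924391005851 0.197221646627194 0.000525924391005851 0.0262962195502926 0.197221646627194 0.000525924391005851 0.0410878430473321 -0.873691894558471 0.0262962195502926 0.164351372189329 0.0262962195502926
0.000525924391005851 0.0262962195502926 0.000525924391005851 0.0111758933088743 0.000525924391005851 0.0262962195502926 0.0157777317301755 0.000525924391005851 0.000525924391005851 0.788886586508777 0.000525924391005851 0.00328702744378657 0.558794665443717 -1.62431748162157 0.164351372189329 0.0262962195502926
0.000525924391005851 0.000525924391005851 0.0262962195502926 0.139698666360929 0.000525924391005851 0.000525924391005851 0.788886586508777 0.000525924391005851 0.000525924391005851 0.197221646627194 0.0262962195502926 0.0410878430473321 0.558794665443717 0.0262962195502926 -1.83402983253516 0.0262962195502926
0.000525924391005851 0.000525924391005851 0.000525924391005851 0.558794665443717 0.000525924391005851 0.000525924391005851 0.0157777317301755 0.0262962195502926 0.000525924391005851 0.0157777317301755 0.000525924391005851 0.164351372189329 0.558794665443717 0.0262962195502926 0.164351372189329 -1.53412144856407
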