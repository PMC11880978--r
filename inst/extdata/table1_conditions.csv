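condition,axin2_absent
SW480,FALSE
AXIN2-/-,TRUE
siAXIN2,FALSE
+/+ #1 ut,FALSE
+/+ #1 G007-LK,FALSE
+/+ #2 ut,FALSE
+/+ #2 G007-LK,FALSE
AXIN2-/- #1 ut,TRUE
AXIN2-/- #1 G007-LK,TRUE
AXIN2-/- #2 ut,TRUE
AXIN2-/- #2 G007-LK,TRUE
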