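H SYNX000001
D Synthetic uniform toy index (values 1..20 in A/L column layout)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.0     2.0     3.0     4.0     5.0     6.0     7.0     8.0     9.0    10.0
    11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0
//
H SYNX000002
D Synthetic constant toy index
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     2.5     2.5     2.5     2.5     2.5     2.5     2.5     2.5     2.5     2.5
     2.5     2.5     2.5     2.5     2.5     2.5     2.5     2.5     2.5     2.5
//
H SYNX000003
D Synthetic index with a missing value (must be dropped)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.0     2.0     3.0     4.0     NA      6.0     7.0     8.0     9.0    10.0
    11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0
//
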