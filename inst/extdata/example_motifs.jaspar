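>SYN0001.1 Gcbx1
A [  2  0  0  2 ]
C [  3 18  0  3 ]
G [  3  0 18  3 ]
T [  2  0  0  2 ]
>SYN0002.1 Gcbx2
A [  1  0  0  0  1 ]
C [  4 16  0 16  4 ]
G [  4  2 18  2  4 ]
T [  1  0  0  0  1 ]
>SYN0003.1 Etsl1
A [  2  0  0 14  2 ]
C [  4  2  0  0  4 ]
G [  4 16 18  2  4 ]
T [  4  0  0  2  4 ]
>SYN0004.1 Repc1
A [  0  2  0  0  2 ]
C [ 16  4 18  0  4 ]
G [  2  4  0 18  4 ]
T [  0  8  0  0  8 ]
>SYN0004.2 Repc1
A [  0  2  0  0 ]
C [ 16  4 18  0 ]
G [  2  4  0 18 ]
T [  0  8  0  0 ]
>SYN0005.1 Repc2
A [  2  0  0  2 ]
C [  2  0 18  2 ]
G [  2 18  0  2 ]
T [ 12  0  0 12 ]
>SYN0006.1 Dual1
A [  2  0  0  0  2 ]
C [  4 18  0  2  4 ]
G [  4  0 18 16  4 ]
T [  2  0  0  0  2 ]
>SYN0007.1 Atrich
A [ 16  2 14  2 16 ]
C [  0  0  2  0  0 ]
G [  0  2  2  2  0 ]
T [  2 14  0 14  2 ]
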