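factor	activity	ntpm
Gcbx1	activator	15.2
Gcbx2	activator	4.1
Etsl1	activator	22.8
Repc1	repressor	12.8
Repc2	repressor	8.0
Dual1	both	26.7
Atrich	repressor	0.4
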