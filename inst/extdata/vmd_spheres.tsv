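peptide	oligomer	size	command
Ab40	10mer	small	draw sphere {53.55 49.24 44.015} radius 25 resolution 50
Ab40	10mer	large	draw sphere {-21.45 49.24 44.015} radius 100 resolution 100
NNFGAIL	10mer	small	draw sphere {4.365 45.515 28.595} radius 25 resolution 50
NNFGAIL	10mer	large	draw sphere {-70.635 45.515 28.595} radius 100 resolution 100
GNNQQNY	10mer	small	draw sphere {5.88 45.285 26.545} radius 25 resolution 50
GNNQQNY	10mer	large	draw sphere {-69.12 45.285 26.545} radius 100 resolution 100
VQIVYK	10mer	small	draw sphere {2.93 43.885 29.12} radius 25 resolution 50
VQIVYK	10mer	large	draw sphere {-72.07 43.885 29.12} radius 100 resolution 100
Ab40	5mer	small	draw sphere {53.55 36.01 44.015} radius 25 resolution 50
Ab40	5mer	large	draw sphere {-21.45 36.01 44.015} radius 100 resolution 100
NNFGAIL	5mer	small	draw sphere {4.365 33.275 28.595} radius 25 resolution 50
NNFGAIL	5mer	large	draw sphere {-70.635 33.275 28.595} radius 100 resolution 100
GNNQQNY	5mer	small	draw sphere {5.88 32.95 26.54} radius 25 resolution 50
GNNQQNY	5mer	large	draw sphere {-69.12 32.95 26.54} radius 100 resolution 100
VQIVYK	5mer	small	draw sphere {2.93 31.725 29.12} radius 25 resolution 50
VQIVYK	5mer	large	draw sphere {-72.07 31.725 29.12} radius 100 resolution 100
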